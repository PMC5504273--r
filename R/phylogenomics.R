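#' Filter all-vs-all translated homology hits
#'
#' Keeps hits from an all-vs-all translated (protein-level) genome
#' comparison that reach at least `min_identity` percent identity over at
#' least `min_length` aligned amino acids with e-value at most `max_e`.
#' Genomes that lose all their self-hits are dropped with a warning, since
#' the Dice distance needs a positive self-score.
#'
#' @param hits Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value`, `bitscore`.
#' @param min_identity Inclusive minimum percent identity (default 30).
#' @param min_length Inclusive minimum aligned length in aa (default 30).
#' @param max_e Inclusive maximum e-value (default 0.01).
#' @return The filtered hit table.
#' @export
filter_homology_hits <- function(hits, min_identity = 30, min_length = 30,
                                 max_e = 0.01) {
  req <- c("query_id", "subject_id", "percent_identity",
           "alignment_length", "e_value", "bitscore")
  stopifnot(all(req %in% names(hits)))
  out <- hits[hits$percent_identity >= min_identity &
                hits$alignment_length >= min_length &
                hits$e_value <= max_e, , drop = FALSE]
  genomes <- union(hits$query_id, hits$subject_id)
  has_self <- genomes %in%
    out$query_id[as.character(out$query_id) == as.character(out$subject_id)]
  if (any(!has_self))
    warning("genome(s) without qualifying self-hits will be dropped from ",
            "similarity: ", paste(genomes[!has_self], collapse = ", "))
  out
}

#' Summed-bitscore genome similarity
#'
#' Sums the bitscores of (filtered) hits per ordered genome pair:
#' `S[A, B]` is the summed bitscore of all hits of genome A against genome
#' B, so `S[A, A]` is the genome's self-score. Genomes without self-hits
#' are dropped (warned), as they cannot enter the Dice distance.
#'
#' @param hits Filtered hit table from [filter_homology_hits()].
#' @return Object of class `"genome_similarity"`: list with `ids` and the
#'   summed-bitscore matrix `S`.
#' @export
genome_similarity <- function(hits) {
  ids <- sort(union(as.character(hits$query_id),
                    as.character(hits$subject_id)))
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  agg <- stats::aggregate(bitscore ~ query_id + subject_id, data = hits, sum)
  S[cbind(as.character(agg$query_id), as.character(agg$subject_id))] <-
    agg$bitscore
  keep <- diag(S) > 0
  if (any(!keep)) {
    warning("dropping genome(s) without self-hits: ",
            paste(ids[!keep], collapse = ", "))
    S <- S[keep, keep, drop = FALSE]
    ids <- ids[keep]
  }
  structure(list(ids = ids, S = S), class = "genome_similarity")
}

#' Dice distance matrix from summed bitscores
#'
#' Converts summed homology bitscores to the Dice genome distance
#' `D[A, B] = 1 - 2 * AB / (AA + BB)`, where `AA` and `BB` are self-scores
#' and `AB` the cross-score. Because a search can be asymmetric, the cross
#' term is symmetrized as `AB_sym = (S[A,B] + S[B,A]) / 2`, which reduces
#' to `AB` for a symmetric search. Distances are clamped to `[0, 1]`; pairs
#' without any cross-hit sit at 1.
#'
#' @param sim A `"genome_similarity"` object (or a plain square matrix of
#'   summed bitscores with dimnames).
#' @return List of class `"dice_distance"` with `ids` and the symmetric
#'   distance matrix `D` (zero diagonal).
#' @export
dice_distance_matrix <- function(sim) {
  S <- if (inherits(sim, "genome_similarity")) sim$S else as.matrix(sim)
  if (any(diag(S) <= 0))
    stop("genome(s) lack self-hits (AA <= 0): ",
         paste(rownames(S)[diag(S) <= 0], collapse = ", "))
  AB <- (S + t(S)) / 2
  denom <- outer(diag(S), diag(S), "+")
  D <- 1 - 2 * AB / denom
  D[D < 0] <- 0
  D[D > 1] <- 1
  diag(D) <- 0
  structure(list(ids = rownames(S), D = D), class = "dice_distance")
}

#' BIONJ tree from a distance matrix
#'
#' Builds an unrooted tree by the BIONJ variant of neighbor joining:
#' standard NJ pair selection (minimum Q criterion) and branch-length
#' formulas, but with the reduced distances formed using the
#' variance-minimizing weight `lambda` of the BIONJ scheme (clamped to
#' `[0, 1]`), where the variance matrix is initialized to the distances
#' and updated alongside them. On additive matrices the reduction is
#' independent of `lambda`, so the result coincides with plain neighbor
#' joining there. Input is validated (symmetric, finite, zero diagonal)
#' and negative branch lengths, which the NJ formulas can produce on
#' non-additive matrices, are clamped to zero; the total clamped length is
#' stored in the `negative_branch_deficit` attribute.
#'
#' @param D A `"dice_distance"` object or a symmetric numeric matrix with
#'   dimnames and zero diagonal.
#' @return An `ape` `phylo` tree with non-negative branch lengths.
#' @export
bionj_tree <- function(D) {
  M <- if (inherits(D, "dice_distance")) D$D else as.matrix(D)
  if (nrow(M) < 3L) stop("need at least 3 taxa")
  if (anyNA(M) || any(!is.finite(M))) stop("distance matrix contains ",
                                           "NA/NaN/Inf entries")
  if (max(abs(M - t(M))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(M)) > 1e-12)) stop("distance matrix diagonal must be 0")
  tree <- bionj_agglomerate(M)
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  if (deficit > 0) {
    message(sprintf("clamped negative branch length totalling %.3g", deficit))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

# BIONJ agglomeration (Gascuel 1997): NJ's Q criterion and branch lengths,
# variance-weighted reduction. Subtrees are carried as Newick fragments and
# the final unrooted (trifurcating) tree is parsed with ape.
bionj_agglomerate <- function(M) {
  D <- unname(M)
  V <- D                      # variances initialized to the distances
  repr <- rownames(M)         # newick fragment per active cluster
  while (length(repr) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- min(idx); j <- max(idx)
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    ks <- setdiff(seq_len(m), c(i, j))
    vij <- V[i, j]
    lambda <- if (vij > 0)
      0.5 + sum(V[j, ks] - V[i, ks]) / (2 * (m - 2) * vij) else 0.5
    lambda <- min(1, max(0, lambda))
    du <- lambda * (D[i, ks] - bi) + (1 - lambda) * (D[j, ks] - bj)
    vu <- lambda * V[i, ks] + (1 - lambda) * V[j, ks] -
      lambda * (1 - lambda) * vij
    fragment <- sprintf("(%s:%.17g,%s:%.17g)", repr[i], bi, repr[j], bj)
    D <- rbind(cbind(D[ks, ks, drop = FALSE], du), c(du, 0))
    V <- rbind(cbind(V[ks, ks, drop = FALSE], vu), c(vu, 0))
    repr <- c(repr[ks], fragment)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                                repr[1L], b1, repr[2L], b2, repr[3L], b3))
}

#' Cut a tree into clusters of bounded diameter
#'
#' Partitions the leaves into clades whose internal path diameter (maximum
#' leaf-to-leaf path length within the clade) does not exceed `max_depth`.
#' Starting from the root, any clade already within the bound becomes a
#' cluster; otherwise its children are examined recursively, so clusters
#' are always monophyletic in the rooted representation of the tree.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param max_depth Non-negative diameter bound (use `Inf` for a single
#'   cluster).
#' @return List of character vectors, each one cluster's leaf labels.
#' @export
extract_clusters <- function(tree, max_depth) {
  if (length(max_depth) != 1L || is.na(max_depth) || max_depth < 0)
    stop("`max_depth` must be a single non-negative number")
  if (is.infinite(max_depth)) return(list(tree$tip.label))
  dmat <- ape::cophenetic.phylo(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  clade_tips <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], clade_tips),
           use.names = FALSE)
  }
  out <- list()
  walk <- function(node) {
    tips <- clade_tips(node)
    diam <- if (length(tips) > 1L)
      max(dmat[tips, tips, drop = FALSE]) else 0
    if (diam <= max_depth) {
      out[[length(out) + 1L]] <<- tips
    } else {
      for (ch in children[[as.character(node)]]) walk(ch)
    }
  }
  walk(root)
  out
}

#' Cluster composition summary
#'
#' Given clusters of genome ids and a flag telling which genomes are novel
#' (for example assembled contigs as opposed to reference genomes), reports
#' per-cluster size and the fraction of novel members — the quantity behind
#' statements like "several clusters are formed exclusively by new
#' genomes".
#'
#' @param clusters List of character vectors from [extract_clusters()].
#' @param novel_ids Character vector of genome ids considered novel.
#' @return Data frame `cluster`, `size`, `n_novel`, `fraction_novel`.
#' @export
cluster_composition <- function(clusters, novel_ids) {
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    tips <- clusters[[i]]
    n_nov <- sum(tips %in% novel_ids)
    data.frame(cluster = i, size = length(tips), n_novel = n_nov,
               fraction_novel = n_nov / length(tips))
  }))
}
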