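#' Abundance-weighted KO profile per sample
#'
#' Sums, per sample, the abundance of each KO (KEGG Orthology group)
#' proportionally to the abundance of the genomes encoding it:
#' `profile[ko, s] = sum_g copies(g, ko) * abundance[g, s]`. For example,
#' in a sample with genomes A, B, C at abundances 1, 5 and 10, each
#' encoding one copy of a KO, that KO's abundance is 1 + 5 + 10 = 16. The
#' profile is exactly linear in the abundance matrix.
#'
#' @param annotations Data frame `genome_id`, `ko_id`, `copies` (positive
#'   integers; unique (genome, ko) pairs). See [annotate_best_hits()].
#' @param abundance An [abundance_matrix()] (either mode); genomes in the
#'   annotation table but absent from the matrix are warned and dropped.
#' @param relative If `TRUE`, each sample column of the profile is
#'   renormalized to sum to 1 (relative KO abundances).
#' @return Numeric matrix, KOs x samples.
#' @export
sample_ko_profile <- function(annotations, abundance, relative = FALSE) {
  req <- c("genome_id", "ko_id", "copies")
  stopifnot(all(req %in% names(annotations)))
  if (any(annotations$copies < 1) ||
      any(annotations$copies != round(annotations$copies)))
    stop("`copies` must be positive integers")
  if (anyDuplicated(annotations[c("genome_id", "ko_id")]))
    stop("(genome_id, ko_id) pairs must be unique")
  extra <- setdiff(annotations$genome_id, rownames(abundance))
  if (length(extra)) {
    warning("annotated genome(s) absent from the abundance matrix: ",
            paste(extra, collapse = ", "))
    annotations <- annotations[!annotations$genome_id %in% extra, ,
                               drop = FALSE]
  }
  kos <- sort(unique(annotations$ko_id))
  C <- matrix(0, length(kos), nrow(abundance),
              dimnames = list(kos, rownames(abundance)))
  C[cbind(annotations$ko_id, annotations$genome_id)] <- annotations$copies
  prof <- C %*% unclass(abundance)
  if (relative) {
    cs <- colSums(prof)
    cs[cs == 0] <- 1
    prof <- sweep(prof, 2L, cs, "/")
  }
  prof
}

#' KO annotation from best protein hits
#'
#' Annotates each protein with the KO of its single best hit (maximum
#' bitscore; ties broken by lower e-value, then lexicographic KO id)
#' against a KO-labelled reference, keeping only hits below the e-value
#' ceiling, and counts copies per (genome, KO).
#'
#' @param hits Data frame `genome_id`, `protein_id`, `ko_id`, `bitscore`,
#'   `e_value` (one row per candidate hit).
#' @param max_e Strict upper bound on e-value (default 1e-5).
#' @return Annotation table `genome_id`, `ko_id`, `copies`.
#' @export
annotate_best_hits <- function(hits, max_e = 1e-5) {
  req <- c("genome_id", "protein_id", "ko_id", "bitscore", "e_value")
  stopifnot(all(req %in% names(hits)))
  h <- hits[hits$e_value < max_e, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(genome_id = character(0), ko_id = character(0),
                      copies = integer(0)))
  h <- h[best_hit_order(h$bitscore, h$e_value, h$ko_id), , drop = FALSE]
  h <- h[!duplicated(h[c("genome_id", "protein_id")]), , drop = FALSE]
  agg <- stats::aggregate(protein_id ~ genome_id + ko_id, data = h,
                          FUN = function(p) length(unique(p)))
  names(agg)[3L] <- "copies"
  agg <- agg[order(agg$genome_id, agg$ko_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
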