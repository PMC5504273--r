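#' Host prediction by genome homology
#'
#' A contig that shares a long, high-identity nucleotide alignment with a
#' microbial genome (typically an integrated prophage or exchanged DNA) is
#' assigned that genome's taxonomy. Only hits with identity strictly above
#' `min_identity` percent over at least `min_length` aligned nucleotides
#' qualify; among qualifying hits the one with the highest bitscore wins
#' (ties: lower e-value, then lexicographic subject id).
#'
#' @param hits Hit table with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value`, `bitscore` (the
#'   tabular BLAST dialect, see [read_blast_table()]).
#' @param hosts Host taxonomy table for the subjects (microbial genomes).
#' @param min_identity Strict lower bound on percent identity (default 80).
#' @param min_length Inclusive minimum alignment length in nt (default 1000).
#' @param method Method label recorded on the assignments (default
#'   `"refseq_homology"`; use `"tara_homology"` when the subjects are
#'   taxonomically annotated environmental contigs).
#' @return Assignment data frame (`query_id`, `method`, `rank`, `taxon`,
#'   `lineage`, `score`, `support`).
#' @export
host_by_genome_homology <- function(hits, hosts, min_identity = 80,
                                    min_length = 1000,
                                    method = "refseq_homology") {
  hosts <- validate_host_table(hosts)
  keep <- hits$percent_identity > min_identity &
    hits$alignment_length >= min_length
  hits <- hits[keep, , drop = FALSE]
  res <- list()
  for (q in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    h <- h[best_hit_order(h$bitscore, h$e_value, h$subject_id), ,
           drop = FALSE]
    h <- h[h$subject_id %in% hosts$genome_id, , drop = FALSE]
    if (nrow(h) == 0L) {
      warning("query ", q, " has qualifying hits only to subjects without ",
              "taxonomy; skipped")
      next
    }
    top <- h[1L, ]
    lin <- host_lineage(hosts, top$subject_id)
    rk <- deepest_rank(lin)
    if (is.na(rk)) next
    res[[q]] <- data.frame(
      query_id = q, method = method, rank = rk, taxon = unname(lin[rk]),
      lineage = lineage_string(lin, rk), score = top$bitscore,
      support = sprintf("best hit %s: %.1f%% id over %d nt",
                        top$subject_id, top$percent_identity,
                        as.integer(top$alignment_length)),
      stringsAsFactors = FALSE)
  }
  empty_assignments(res)
}

#' Hierarchical bitscore-voting taxonomy for contigs
#'
#' Classifies a contig from the best protein-level hits of its predicted
#' proteins against a taxonomically annotated reference. After discarding
#' hits with e-value >= `max_e` or identity <= `min_identity`, the best hit
#' per protein is kept and bitscores are summed per contig. Contigs whose
#' total falls below `min_total_bitscore` are left unclassified. The
#' classification then descends domain to species, fixing a taxon at each
#' rank while some taxon holds at least `consistency` of the contig's total
#' (post-filter) bitscore, and stops at the first rank where none does.
#' Contigs that resolve to a viral or eukaryotic domain, or that cannot be
#' classified at domain, are flagged `"discarded"` (they cannot serve as
#' host evidence).
#'
#' @param hits Data frame with columns `contig_id`, `protein_id`,
#'   `bitscore`, `e_value`, `percent_identity` plus rank columns
#'   ([taxonomic_ranks()]) giving each hit's subject lineage.
#' @param consistency Bitscore share required to fix a taxon (default 0.8).
#' @param min_total_bitscore Minimum summed bitscore per contig (default
#'   1000).
#' @param max_e Strict upper bound on e-value (default 1e-5).
#' @param min_identity Strict lower bound on percent identity (default 30).
#' @return Data frame with one row per contig: rank columns with the fixed
#'   taxa (`NA` below the stopping rank), `classified_rank`,
#'   `total_bitscore`, `status` in `{"classified", "unclassified",
#'   "discarded"}`.
#' @export
classify_contig_taxonomy <- function(hits, consistency = 0.8,
                                     min_total_bitscore = 1000,
                                     max_e = 1e-5, min_identity = 30) {
  req <- c("contig_id", "protein_id", "bitscore", "e_value",
           "percent_identity")
  stopifnot(all(req %in% names(hits)))
  hits <- hits[hits$e_value < max_e & hits$percent_identity > min_identity, ,
               drop = FALSE]
  contigs <- sort(unique(hits$contig_id))
  rows <- lapply(contigs, function(cid) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    # best hit per protein
    h <- h[best_hit_order(h$bitscore, h$e_value,
                          if ("subject_id" %in% names(h)) h$subject_id
                          else h$protein_id), , drop = FALSE]
    h <- h[!duplicated(h$protein_id), , drop = FALSE]
    total <- sum(h$bitscore)
    out <- setNames(as.list(rep(NA_character_, length(ranks_order))),
                    ranks_order)
    if (total < min_total_bitscore)
      return(data.frame(contig_id = cid, out, classified_rank = NA,
                        total_bitscore = total, status = "unclassified",
                        stringsAsFactors = FALSE))
    fixed_rank <- NA_character_
    for (rk in ranks_order) {
      if (!rk %in% names(h)) break
      taxa <- as.character(h[[rk]])
      ok <- !is.na(taxa) & nzchar(taxa)
      if (!any(ok)) break
      share <- tapply(h$bitscore[ok], taxa[ok], sum) / total
      top <- which.max(share)
      if (share[top] < consistency) break
      out[[rk]] <- names(share)[top]
      fixed_rank <- rk
    }
    status <- if (is.na(fixed_rank)) "discarded"
      else if (out$domain %in% c("Viruses", "Eukaryota")) "discarded"
      else "classified"
    data.frame(contig_id = cid, out, classified_rank = fixed_rank,
               total_bitscore = total, status = status,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(contig_id = character(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Host prediction from CRISPR spacer matches
#'
#' A CRISPR spacer found in a microbial genome is a record of a past
#' infection; a near-exact match of such a spacer inside a viral contig
#' links the contig to the spacer's source organism. Because spacers are
#' only ~20-30 nt, matches are accepted only with at most
#' `max_mismatch_gaps` combined mismatches and gaps and full spacer
#' coverage (alignment length at least spacer length minus gaps).
#'
#' @param spacer_hits Hit table of spacers (queries) against contigs
#'   (subjects); needs `query_id`, `subject_id`, `mismatches`, `gaps`,
#'   `alignment_length` and `spacer_length` (length of the spacer query).
#' @param spacer_sources Data frame `spacer_id`, `source_genome_id` mapping
#'   each spacer to the microbial genome it was mined from.
#' @param hosts Host taxonomy table for the source genomes.
#' @param max_mismatch_gaps Maximum mismatches + gaps (default 2).
#' @return Assignment data frame, one row per (contig, source lineage);
#'   `support` counts concordant spacers and a `conflict` column flags
#'   contigs whose spacers point to more than one phylum.
#' @export
host_by_crispr <- function(spacer_hits, spacer_sources, hosts,
                           max_mismatch_gaps = 2) {
  if (!"spacer_length" %in% names(spacer_hits))
    stop("`spacer_hits` must contain a `spacer_length` column ",
         "(full spacer coverage is required)")
  hosts <- validate_host_table(hosts)
  keep <- (spacer_hits$mismatches + spacer_hits$gaps) <= max_mismatch_gaps &
    spacer_hits$alignment_length >=
      spacer_hits$spacer_length - spacer_hits$gaps
  h <- spacer_hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(empty_assignments(list(), conflict = TRUE))
  h$source <- spacer_sources$source_genome_id[
    match(h$query_id, spacer_sources$spacer_id)]
  if (anyNA(h$source))
    stop("spacer(s) without a source genome in `spacer_sources`: ",
         paste(unique(h$query_id[is.na(h$source)]), collapse = ", "))
  res <- list()
  for (cid in sort(unique(h$subject_id))) {
    hc <- h[h$subject_id == cid, , drop = FALSE]
    lineages <- lapply(unique(hc$source), function(g) host_lineage(hosts, g))
    names(lineages) <- unique(hc$source)
    phyla <- unique(na.omit(vapply(lineages, `[[`, "", "phylum")))
    conflict <- length(phyla) > 1L
    if (conflict)
      warning("contig ", cid, " has CRISPR evidence from multiple phyla: ",
              paste(phyla, collapse = ", "))
    for (g in names(lineages)) {
      lin <- lineages[[g]]
      rk <- deepest_rank(lin)
      if (is.na(rk)) next
      n_sp <- length(unique(hc$query_id[hc$source == g]))
      res[[paste(cid, g)]] <- data.frame(
        query_id = cid, method = "crispr", rank = rk,
        taxon = unname(lin[rk]), lineage = lineage_string(lin, rk),
        score = min(hc$mismatches[hc$source == g] +
                      hc$gaps[hc$source == g]),
        support = sprintf("%d spacer(s) from %s", n_sp, g),
        conflict = conflict, stringsAsFactors = FALSE)
    }
  }
  empty_assignments(res, conflict = TRUE)
}

#' Host prediction from tRNA matches
#'
#' Phages often carry tRNAs acquired from their hosts; a near-identical,
#' near-full-length match of a contig's tRNA in a microbial genome suggests
#' that genome's lineage as the host. The best hit with identity >=
#' `min_identity` percent and query (tRNA) coverage >= `min_coverage`
#' defines the host.
#'
#' @param trna_hits Hit table of contig tRNAs (queries) against microbial
#'   genomes (subjects); requires a `subject_coverage` column holding the
#'   covered fraction of the tRNA query in `[0, 1]`, plus `query_id`,
#'   `subject_id`, `percent_identity`, `e_value`, `bitscore` and optionally
#'   `contig_id` (defaults to `query_id`).
#' @param hosts Host taxonomy table for the subject genomes.
#' @param min_identity Inclusive minimum percent identity (default 90).
#' @param min_coverage Inclusive minimum coverage fraction (default 0.9).
#' @return Assignment data frame as in [host_by_genome_homology()].
#' @export
host_by_trna <- function(trna_hits, hosts, min_identity = 90,
                         min_coverage = 0.9) {
  if (!"subject_coverage" %in% names(trna_hits))
    stop("`trna_hits` must contain a `subject_coverage` column ",
         "(fraction of the tRNA query covered by the alignment)")
  hosts <- validate_host_table(hosts)
  h <- trna_hits[trna_hits$percent_identity >= min_identity &
                   trna_hits$subject_coverage >= min_coverage, ,
                 drop = FALSE]
  if (!"contig_id" %in% names(h)) h$contig_id <- h$query_id
  res <- list()
  for (cid in sort(unique(h$contig_id))) {
    hc <- h[h$contig_id == cid, , drop = FALSE]
    hc <- hc[best_hit_order(hc$bitscore, hc$e_value, hc$subject_id), ,
             drop = FALSE]
    hc <- hc[hc$subject_id %in% hosts$genome_id, , drop = FALSE]
    if (nrow(hc) == 0L) next
    top <- hc[1L, ]
    lin <- host_lineage(hosts, top$subject_id)
    rk <- deepest_rank(lin)
    if (is.na(rk)) next
    res[[cid]] <- data.frame(
      query_id = cid, method = "trna", rank = rk, taxon = unname(lin[rk]),
      lineage = lineage_string(lin, rk), score = top$bitscore,
      support = sprintf("tRNA best hit %s: %.1f%% id, %.0f%% coverage",
                        top$subject_id, top$percent_identity,
                        100 * top$subject_coverage),
      stringsAsFactors = FALSE)
  }
  empty_assignments(res)
}

#' Combine host assignments from all methods into a summary table
#'
#' Stacks per-method assignment tables and tabulates, per predicted taxon,
#' how many queries each method assigned to it (methods are counted
#' independently; a query predicted by two methods contributes to both
#' columns). Rows are ordered by total count.
#'
#' @param ... Assignment data frames as returned by the `host_by_*` and
#'   [predict_hosts()] functions (or a single list of them).
#' @return List with `summary` (taxon x method count data frame, plus
#'   `total`) and `assignments` (the stacked long table).
#' @export
consolidate_predictions <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !is.data.frame(parts[[1L]])) parts <- parts[[1L]]
  parts <- Filter(function(p) is.data.frame(p) && nrow(p) > 0, parts)
  methods <- c("refseq_homology", "tara_homology", "crispr", "trna",
               "network")
  base_cols <- c("query_id", "method", "rank", "taxon", "lineage", "score",
                 "support")
  long <- if (length(parts))
    do.call(rbind, c(lapply(parts, function(p) p[base_cols]),
                     make.row.names = FALSE))
  else
    stats::setNames(data.frame(matrix(ncol = length(base_cols), nrow = 0)),
                    base_cols)
  if (nrow(long) == 0L) {
    summ <- data.frame(taxon = character(0))
    for (m in methods) summ[[m]] <- integer(0)
    summ$total <- integer(0)
    return(list(summary = summ, assignments = long))
  }
  tab <- table(long$taxon, factor(long$method, levels = methods))
  summ <- data.frame(taxon = rownames(tab),
                     as.data.frame.matrix(tab),
                     stringsAsFactors = FALSE, row.names = NULL)
  summ$total <- rowSums(summ[methods])
  summ <- summ[order(-summ$total, summ$taxon), , drop = FALSE]
  rownames(summ) <- NULL
  list(summary = summ, assignments = long)
}

empty_assignments <- function(res, conflict = FALSE) {
  if (length(res)) return(do.call(rbind, c(res, make.row.names = FALSE)))
  out <- data.frame(query_id = character(0), method = character(0),
                    rank = character(0), taxon = character(0),
                    lineage = character(0), score = numeric(0),
                    support = character(0), stringsAsFactors = FALSE)
  if (conflict) out$conflict <- logical(0)
  out
}
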