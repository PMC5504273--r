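#' Construct an abundance matrix
#'
#' A genome-by-sample abundance matrix is the substrate of every downstream
#' analysis (correlation networks, virus/host ratios, enrichment tests). It
#' is a plain numeric matrix with genome ids as row names, sample ids as
#' column names and a `mode` attribute that records whether entries are
#' (weighted) read counts or per-sample relative abundances.
#'
#' @param values Numeric matrix, genomes in rows, samples in columns; must
#'   carry row and column names and contain no negative values.
#' @param mode Either `"counts"` or `"relative"`.
#' @return The matrix with class `"abundance_matrix"` and a `mode` attribute.
#' @export
abundance_matrix <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have genome row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("genome ids (row names) must be unique")
  if (any(values < 0)) stop("abundances must be non-negative")
  if (mode == "relative") {
    cs <- colSums(values)
    bad <- cs > 0 & abs(cs - 1) > 1e-9
    if (any(bad))
      stop("relative-mode columns must sum to 1 (or be all zero); offending: ",
           paste(colnames(values)[bad], collapse = ", "))
  }
  structure(values, mode = mode, class = c("abundance_matrix", class(values)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s]: %d genomes x %d samples\n",
              abundance_mode(x), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  invisible(x)
}

#' @rdname abundance_matrix
#' @param x An `abundance_matrix`.
#' @export
abundance_mode <- function(x) {
  m <- attr(x, "mode")
  if (is.null(m)) stop("matrix carries no abundance mode attribute")
  m
}

#' Weighted assignment of reads to genomes
#'
#' Turns a read-to-genome alignment table into a count-mode abundance matrix.
#' Within each sample, a read aligned to a single genome contributes 1.0 to
#' that genome. A read aligned ambiguously to genomes `g1..gk` is split in
#' proportion to the unambiguous evidence: genome `g_i` receives
#' `u_i / sum(u_j)` where `u_i` is the number of unambiguous reads of `g_i`
#' in that sample. When no candidate genome has any unambiguous read the
#' read is split evenly, `1/k` each, so that the total assigned weight per
#' sample always equals the number of distinct reads exactly.
#'
#' @param alignments Data frame with columns `read_id`, `genome_id`,
#'   `sample_id`; one row per (read, candidate genome) alignment. A read is
#'   ambiguous precisely when it has more than one row within its sample.
#' @param genome_ids Optional character vector fixing the row universe (and
#'   order) of the output; defaults to the sorted genomes seen in the table.
#' @return A counts-mode [abundance_matrix()].
#' @export
assign_reads <- function(alignments, genome_ids = NULL) {
  req <- c("read_id", "genome_id", "sample_id")
  if (!is.data.frame(alignments) || !all(req %in% names(alignments)))
    stop("`alignments` needs columns read_id, genome_id, sample_id")
  if (nrow(alignments) == 0L) stop("`alignments` is empty")
  dt <- data.table::as.data.table(alignments[req])
  for (cn in req) data.table::set(dt, j = cn, value = as.character(dt[[cn]]))
  if (anyDuplicated(dt, by = req) > 0L)
    stop("duplicate (read_id, genome_id, sample_id) rows in alignment table")

  genomes <- sort(unique(dt$genome_id))
  if (!is.null(genome_ids)) {
    missing <- setdiff(genomes, genome_ids)
    if (length(missing))
      stop("alignments reference genomes absent from `genome_ids`: ",
           paste(missing, collapse = ", "))
    genomes <- genome_ids
  }
  samples <- sort(unique(dt$sample_id))
  out <- matrix(0, nrow = length(genomes), ncol = length(samples),
                dimnames = list(genomes, samples))

  dt[, n_hits := .N, by = .(sample_id, read_id)]

  uniq <- dt[n_hits == 1L, .(n_unique = .N), by = .(sample_id, genome_id)]
  if (nrow(uniq))
    out[cbind(uniq$genome_id, uniq$sample_id)] <- uniq$n_unique

  amb <- dt[n_hits > 1L]
  if (nrow(amb)) {
    amb <- merge(amb, uniq, by = c("sample_id", "genome_id"), all.x = TRUE)
    amb[is.na(n_unique), n_unique := 0L]
    amb[, weight := {
      s <- sum(n_unique)
      if (s > 0) n_unique / s else rep(1 / .N, .N)
    }, by = .(sample_id, read_id)]
    add <- amb[, .(weight = sum(weight)), by = .(sample_id, genome_id)]
    idx <- cbind(add$genome_id, add$sample_id)
    out[idx] <- out[idx] + add$weight
  }
  abundance_matrix(out, mode = "counts")
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample column is divided by its sum; all-zero columns are preserved
#' as zero (with a warning, since they usually indicate an empty sample).
#'
#' @param matrix A counts-mode [abundance_matrix()].
#' @return A relative-mode [abundance_matrix()].
#' @export
to_relative <- function(matrix) {
  if (abundance_mode(matrix) != "counts")
    stop("`to_relative()` expects a counts-mode matrix")
  cs <- colSums(matrix)
  zero <- cs == 0
  if (any(zero))
    warning("all-zero sample column(s) left as zero: ",
            paste(colnames(matrix)[zero], collapse = ", "))
  cs[zero] <- 1
  abundance_matrix(sweep(unclass(matrix), 2L, cs, "/"), mode = "relative")
}

#' Prevalence filter
#'
#' Removes genomes detected (abundance strictly greater than zero) in fewer
#' than `min_fraction` of the samples. Sparse genomes are a known source of
#' spurious compositional correlations, so this filter is applied before
#' network inference; the default matches the 40% threshold used for the
#' co-occurrence analysis.
#'
#' @param matrix An [abundance_matrix()] (either mode).
#' @param min_fraction Minimum fraction of samples, in `[0, 1]`, in which a
#'   genome must be detected to be retained.
#' @return The matrix restricted to retained genomes; samples unchanged.
#' @export
filter_by_prevalence <- function(matrix, min_fraction = 0.4) {
  stopifnot(length(min_fraction) == 1L, min_fraction >= 0, min_fraction <= 1)
  mode <- abundance_mode(matrix)
  detected <- rowSums(unclass(matrix) > 0)
  keep <- detected >= min_fraction * ncol(matrix)
  if (!any(keep))
    warning("prevalence filter removed every genome")
  abundance_matrix(unclass(matrix)[keep, , drop = FALSE], mode = mode)
}

#' Per-genome prevalence
#'
#' @param matrix An [abundance_matrix()].
#' @return Named vector of the fraction of samples in which each genome has
#'   abundance > 0.
#' @export
prevalence <- function(matrix) rowMeans(unclass(matrix) > 0)
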