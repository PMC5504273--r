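#' Virus/host ratio records
#'
#' The virus/host ratio (VHR) of a taxon in a sample is the summed relative
#' abundance of the viruses assigned to that taxon divided by the taxon's
#' abundance in the paired cellular metagenome. Records with zero host
#' abundance are kept but flagged undefined and excluded from downstream
#' correlations.
#'
#' @param viral_ab [abundance_matrix()] of viral genomes x samples.
#' @param host_ab Matrix of host taxa x samples (rows named by taxa at
#'   `rank`), from the paired cellular metagenomes.
#' @param assignments Assignment data frame (from any of the host
#'   prediction methods, or known hosts) with columns `query_id` and the
#'   taxon at `rank` (taken from `taxon` when `rank` matches the
#'   assignment's rank, else parsed from `lineage`).
#' @param rank Rank at which viruses are aggregated (`"genus"` or
#'   `"phylum"`).
#' @return Data frame of VHR records: `taxon`, `rank`, `sample_id`,
#'   `host_abundance`, `viral_abundance`, `vhr`, `defined`.
#' @export
virus_host_ratio <- function(viral_ab, host_ab, assignments,
                             rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  samples <- intersect(colnames(viral_ab), colnames(host_ab))
  if (length(samples) == 0L)
    stop("viral and host matrices share no sample ids")
  tax <- assignment_taxon_at(assignments, rank)
  tax <- tax[!is.na(tax$taxon) & tax$query_id %in% rownames(viral_ab), ,
             drop = FALSE]
  taxa <- intersect(unique(tax$taxon), rownames(host_ab))
  rows <- list()
  for (tx in taxa) {
    vir <- tax$query_id[tax$taxon == tx]
    v <- colSums(unclass(viral_ab)[vir, samples, drop = FALSE])
    h <- host_ab[tx, samples]
    rows[[tx]] <- data.frame(
      taxon = tx, rank = rank, sample_id = samples,
      host_abundance = as.numeric(h), viral_abundance = as.numeric(v),
      vhr = ifelse(h > 0, v / h, NA_real_),
      defined = h > 0, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(taxon = character(0), rank = character(0),
                      sample_id = character(0), host_abundance = numeric(0),
                      viral_abundance = numeric(0), vhr = numeric(0),
                      defined = logical(0)))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  n_undef <- sum(!out$defined)
  if (n_undef) message(n_undef, " record(s) undefined (zero host abundance)")
  out
}

# taxon at `rank` from an assignment table: use `taxon` when the row's rank
# matches, otherwise read position `rank` of the `;`-joined lineage
assignment_taxon_at <- function(assignments, rank) {
  pos <- match(rank, ranks_order)
  taxon <- ifelse(assignments$rank == rank, assignments$taxon, NA_character_)
  need <- is.na(taxon)
  if (any(need)) {
    parts <- strsplit(assignments$lineage[need], ";", fixed = TRUE)
    taxon[need] <- vapply(parts, function(p)
      if (length(p) >= pos) p[pos] else NA_character_, "")
  }
  data.frame(query_id = assignments$query_id, taxon = taxon,
             stringsAsFactors = FALSE)
}

#' Association between host abundance and the virus/host ratio
#'
#' Spearman rank correlation between host abundance and VHR, per taxon
#' (taxa with fewer than `min_n` defined records are skipped) and pooled
#' over all defined records. A negative pooled correlation is the signature
#' of reduced lysis at high host density (Piggyback-the-Winner); an
#' approximate 95% confidence interval is attached via the Fisher
#' z-transform.
#'
#' @param records VHR record data frame from [virus_host_ratio()].
#' @param min_n Minimum defined records per taxon (default 5).
#' @return List with `per_taxon` (data frame `taxon`, `n`, `rho`,
#'   `p_value`) and `pooled` (list `n`, `rho`, `p_value`, `ci_low`,
#'   `ci_high`).
#' @export
vhr_association <- function(records, min_n = 5L) {
  rec <- records[records$defined, , drop = FALSE]
  sp <- function(x, y) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  per <- lapply(split(rec, rec$taxon), function(r) {
    if (nrow(r) < min_n) return(NULL)
    s <- sp(r$host_abundance, r$vhr)
    data.frame(taxon = r$taxon[1L], n = nrow(r), rho = s$rho,
               p_value = s$p, stringsAsFactors = FALSE)
  })
  per <- Filter(Negate(is.null), per)
  per <- if (length(per)) do.call(rbind, c(per, make.row.names = FALSE))
         else NULL
  if (is.null(per))
    per <- data.frame(taxon = character(0), n = integer(0),
                      rho = numeric(0), p_value = numeric(0))
  s <- sp(rec$host_abundance, rec$vhr)
  n <- nrow(rec)
  ci <- c(NA_real_, NA_real_)
  if (!is.na(s$rho) && n > 3 && abs(s$rho) < 1) {
    z <- atanh(s$rho); se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * 1.96 * se)
  }
  list(per_taxon = per,
       pooled = list(n = n, rho = s$rho, p_value = s$p,
                     ci_low = ci[1L], ci_high = ci[2L]))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments over the pooled (average) ranks; handles ties. Mirrors the
# two-sided convention of stats::wilcox.test: double the smaller tail,
# capped at 1.
mann_whitney_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(nx + ny, nx)
  u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  eps <- 1e-9
  p <- if (u_obs > mu) mean(u_all >= u_obs - eps)
       else mean(u_all <= u_obs + eps)
  min(2 * p, 1)
}

# Mann-Whitney p-value: exact enumeration when both groups are small,
# normal approximation with tie correction otherwise.
mann_whitney_p <- function(x, y, exact_max = 8L) {
  if (length(x) <= exact_max && length(y) <= exact_max)
    return(mann_whitney_exact_p(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

#' Group-wise differential abundance with FDR control
#'
#' Compares every feature (genome, contig, KO or taxon row of the matrix)
#' between two sample groups with the two-sided Mann-Whitney test —
#' exact enumeration when both groups have at most 8 samples, normal
#' approximation with tie correction otherwise — and corrects the p-values
#' across features with the Benjamini-Hochberg step-up. Features with
#' corrected p below `alpha` are significant; the enriched group is the one
#' with the higher median (ties broken by the higher mean; a residual tie
#' is flagged `NA`).
#'
#' @param matrix Numeric features x samples matrix (an
#'   [abundance_matrix()] or a KO profile).
#' @param groups Either a named character/factor vector over the sample
#'   ids, or a data frame `sample_id`, `group`; exactly two levels with at
#'   least 3 samples each.
#' @param alpha Significance level on the corrected p-value (default 0.05).
#' @return Data frame: `feature_id`, `group_enriched`, `p_raw`, `q_fdr`,
#'   `significant`.
#' @export
differential_abundance <- function(matrix, groups, alpha = 0.05) {
  m <- unclass(matrix)
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  groups <- groups[colnames(m)]
  if (anyNA(groups)) stop("every sample column needs a group label")
  lv <- unique(unname(groups))
  if (length(lv) != 2L) stop("exactly two group levels required, got ",
                             length(lv))
  idx1 <- which(groups == lv[1L]); idx2 <- which(groups == lv[2L])
  if (length(idx1) < 3L || length(idx2) < 3L)
    stop("both groups need at least 3 samples")
  p <- vapply(seq_len(nrow(m)), function(i)
    mann_whitney_p(m[i, idx1], m[i, idx2]), 0)
  q <- p.adjust(p, method = "BH")
  enriched <- vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, idx1]; b <- m[i, idx2]
    if (median(a) > median(b)) return(lv[1L])
    if (median(b) > median(a)) return(lv[2L])
    if (mean(a) > mean(b)) return(lv[1L])
    if (mean(b) > mean(a)) return(lv[2L])
    NA_character_
  }, "")
  data.frame(feature_id = rownames(m), group_enriched = enriched,
             p_raw = p, q_fdr = q, significant = q < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
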