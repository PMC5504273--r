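#' Predict virus hosts from the co-occurrence network
#'
#' The network host-prediction method: a query virus (one without a known
#' host) is assigned the host of the reference virus (one with a known host)
#' with which it shows the strongest positive abundance correlation,
#' provided that correlation reaches the cutoff. The rationale is that
#' viruses infecting the same organism compete for it and therefore
#' co-occur. The default cutoff of +0.6 trades coverage for precision.
#'
#' Ties at the maximum correlation are resolved only when every tied
#' reference agrees at the requested rank; otherwise the query is left
#' unassigned and the tie is recorded in the `ties` attribute. Negative
#' correlations are never used for prediction.
#'
#' @param network A `"sparcc_network"` from [sparcc_correlations()] (or any
#'   list with elements `rho` and `genome_ids`).
#' @param hosts Host taxonomy data frame: `genome_id` plus rank columns
#'   (see [taxonomic_ranks()]); rows are the reference viruses.
#' @param rank Rank at which to report the prediction (default `"genus"`).
#' @param cutoff Minimum correlation for an assignment (default 0.6).
#' @return Data frame with columns `query_id`, `method`, `rank`, `taxon`,
#'   `lineage`, `score`, `support`; attribute `ties` lists queries dropped
#'   by the tie rule.
#' @export
predict_hosts <- function(network, hosts, rank = "genus", cutoff = 0.6) {
  rank <- match.arg(rank, ranks_order)
  hosts <- validate_host_table(hosts)
  rho <- network$rho
  refs <- intersect(network$genome_ids, hosts$genome_id)
  queries <- setdiff(network$genome_ids, refs)
  if (length(refs) == 0L) stop("no reference genome in the network carries ",
                               "a host label")
  res <- list(); ties <- character(0)
  for (q in queries) {
    r <- rho[q, refs]
    best <- max(r)
    if (!(best >= cutoff)) next
    tied <- refs[r >= best - 1e-12]
    assigned <- lapply(tied, function(g) {
      lin <- host_lineage(hosts, g)
      use_rank <- rank
      if (is.na(lin[rank])) {
        use_rank <- deepest_rank(lin)   # fall back, flagged in support
        if (is.na(use_rank)) return(NULL)
      }
      list(taxon = unname(lin[use_rank]), rank = use_rank, lineage = lin)
    })
    assigned <- Filter(Negate(is.null), assigned)
    if (length(assigned) == 0L) next
    taxa <- vapply(assigned, `[[`, "", "taxon")
    if (length(unique(taxa)) > 1L) {        # discordant tie: abstain
      ties <- c(ties, q)
      next
    }
    a <- assigned[[1L]]
    support <- sprintf("rho=%.4f to %s", best,
                       paste(tied, collapse = ","))
    if (a$rank != rank)
      support <- paste0(support, "; rank fallback to ", a$rank)
    res[[q]] <- data.frame(
      query_id = q, method = "network", rank = a$rank, taxon = a$taxon,
      lineage = lineage_string(a$lineage, a$rank), score = best,
      support = support, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE))
         else data.frame(query_id = character(0), method = character(0),
                         rank = character(0), taxon = character(0),
                         lineage = character(0), score = numeric(0),
                         support = character(0))
  attr(out, "ties") <- ties
  out
}

#' Accuracy of network host prediction on labelled references
#'
#' Leave-self-out calibration of the network method: each reference virus
#' with a known host is treated as a query, predicted from the strongest
#' correlation to any *other* reference, and scored correct when the
#' predicted taxon matches its own at the given rank. Sweeping the minimum
#' correlation cutoff yields the accuracy/coverage trade-off that justifies
#' the default +0.6 cutoff.
#'
#' @inheritParams predict_hosts
#' @param cutoffs Ascending grid of cutoffs to evaluate.
#' @return Data frame with one row per cutoff: `cutoff`, `n_predicted`,
#'   `accuracy` (`NA` where nothing is predicted).
#' @export
evaluate_reference_accuracy <- function(network, hosts, rank = "phylum",
                                        cutoffs = seq(0, 0.9, by = 0.1)) {
  rank <- match.arg(rank, ranks_order)
  hosts <- validate_host_table(hosts)
  rho <- network$rho
  refs <- intersect(network$genome_ids, hosts$genome_id)
  if (length(refs) < 2L) stop("need at least two labelled references")
  taxa <- vapply(refs, function(g) unname(host_lineage(hosts, g)[rank]), "")
  names(taxa) <- refs
  if (all(is.na(taxa))) stop("no reference carries a taxon at rank ", rank)

  best_score <- numeric(length(refs)); correct <- logical(length(refs))
  for (i in seq_along(refs)) {
    others <- setdiff(refs, refs[i])
    r <- rho[refs[i], others]
    b <- max(r)
    tied <- others[r >= b - 1e-12]
    pred <- unique(taxa[tied])
    best_score[i] <- b
    correct[i] <- length(pred) == 1L && !is.na(pred) &&
      !is.na(taxa[i]) && pred == taxa[i]
  }
  out <- lapply(sort(cutoffs), function(ct) {
    sel <- best_score >= ct
    data.frame(cutoff = ct, n_predicted = sum(sel),
               accuracy = if (any(sel)) mean(correct[sel]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Census of correlation signs among same-host reference viruses
#'
#' Counts, among pairs of labelled reference viruses sharing the same taxon
#' at `rank`, how many correlate positively versus negatively. Pairs with
#' `|rho|` below `min_abs` are considered too close to zero for a reliable
#' sign call and are excluded.
#'
#' @inheritParams predict_hosts
#' @param min_abs Minimum absolute correlation for a sign call (default 0.3).
#' @return List with `n_positive`, `n_negative`, `n_excluded`.
#' @export
same_host_correlation_census <- function(network, hosts, rank = "genus",
                                         min_abs = 0.3) {
  rank <- match.arg(rank, ranks_order)
  hosts <- validate_host_table(hosts)
  rho <- network$rho
  refs <- intersect(network$genome_ids, hosts$genome_id)
  taxa <- vapply(refs, function(g) unname(host_lineage(hosts, g)[rank]), "")
  n_pos <- 0L; n_neg <- 0L; n_exc <- 0L
  if (length(refs) >= 2L) {
    for (i in seq_len(length(refs) - 1L)) for (j in (i + 1L):length(refs)) {
      if (is.na(taxa[i]) || is.na(taxa[j]) || taxa[i] != taxa[j]) next
      r <- rho[refs[i], refs[j]]
      if (r >= min_abs) n_pos <- n_pos + 1L
      else if (r <= -min_abs) n_neg <- n_neg + 1L
      else n_exc <- n_exc + 1L
    }
  }
  list(n_positive = n_pos, n_negative = n_neg, n_excluded = n_exc)
}
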