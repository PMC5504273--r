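#' Dirichlet resampling of component fractions
#'
#' Sequencing counts carry only relative information; SparCC-style inference
#' therefore works on fractions drawn from the posterior of each sample's
#' composition under a uniform prior, i.e. Dirichlet(counts + 1) per sample.
#' The +1 pseudocount makes zero counts usable.
#'
#' @param counts Counts-mode [abundance_matrix()] (or plain non-negative
#'   integer matrix, genomes x samples).
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return Matrix of fractions, same shape as `counts`; columns sum to 1.
#' @export
estimate_fractions <- function(counts, seed) {
  x <- unclass(counts)
  if (!is.null(attr(counts, "mode")) && abundance_mode(counts) != "counts")
    stop("fractions are estimated from counts; pass a counts-mode matrix")
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8))
    stop("`counts` must be non-negative integers (counts mode)")
  set.seed(as.integer(seed))
  g <- matrix(rgamma(length(x), shape = x + 1, rate = 1),
              nrow = nrow(x), dimnames = dimnames(x))
  sweep(g, 2L, colSums(g), "/")
}

#' Variance matrix of pairwise log-ratios
#'
#' The basic SparCC statistic: `t[i, j]` is the variance across samples of
#' `log(x_i / x_j)`. Computed from the covariance matrix of the
#' log-fractions, `t_ij = V_ii + V_jj - 2 V_ij`.
#'
#' @param fractions Strictly positive fractions matrix (genomes x samples).
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
logratio_variance_matrix <- function(fractions) {
  if (ncol(fractions) < 3L)
    stop("need at least 3 samples for log-ratio variances")
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  L <- log(fractions)
  V <- stats::cov(t(L))
  t_mat <- outer(diag(V), diag(V), "+") - 2 * V
  t_mat[t_mat < 0] <- 0      # numerical noise on near-proportional pairs
  diag(t_mat) <- 0
  dimnames(t_mat) <- list(rownames(fractions), rownames(fractions))
  t_mat
}

#' Solve for basis (per-genome) variances under the sparsity approximation
#'
#' Under the SparCC sparsity assumption (most pairs uncorrelated, so the sum
#' of correlation terms is negligible), the row sums of the log-ratio
#' variance matrix satisfy the linear system
#' `sum_j t[i, j] = (d - 1) w2_i + sum_{j != i} w2_j`
#' in the basis variances `w2`. Excluded pairs (identified as strongly
#' correlated during exclusion iterations) are removed from both the sums
#' and the coefficient matrix. Non-positive solutions, which can arise when
#' the approximation is violated, are clamped to `1e-8` with a warning.
#'
#' @param t_mat Log-ratio variance matrix from [logratio_variance_matrix()].
#' @param excluded_pairs Two-column integer matrix of genome index pairs to
#'   exclude (order within a pair irrelevant), or `NULL`.
#' @return List with `omega2` (basis variances) and `excluded_pairs`.
#' @export
solve_basis_variances <- function(t_mat, excluded_pairs = NULL) {
  d <- nrow(t_mat)
  if (d < 2L) stop("need at least two components")
  M <- matrix(1, d, d)
  diag(M) <- d - 1
  b <- rowSums(t_mat)
  if (!is.null(excluded_pairs) && nrow(excluded_pairs)) {
    for (k in seq_len(nrow(excluded_pairs))) {
      i <- excluded_pairs[k, 1L]; j <- excluded_pairs[k, 2L]
      M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
      M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
      b[i] <- b[i] - t_mat[i, j]; b[j] <- b[j] - t_mat[i, j]
    }
  }
  omega2 <- tryCatch(solve(M, b), error = function(e)
    stop("basis variance system is singular (too many excluded pairs ",
         "for its dimension): ", conditionMessage(e)))
  if (any(omega2 <= 0)) {
    warning(sum(omega2 <= 0),
            " non-positive basis variance(s) clamped to 1e-8")
    omega2[omega2 <= 0] <- 1e-8
  }
  names(omega2) <- rownames(t_mat)
  list(omega2 = omega2, excluded_pairs = excluded_pairs)
}

# correlations implied by basis variances and log-ratio variances
rho_from_basis <- function(omega2, t_mat) {
  o <- outer(omega2, omega2, "+")
  rho <- (o - t_mat) / (2 * sqrt(outer(omega2, omega2)))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

#' SparCC-style compositional correlation network
#'
#' Infers correlations between genome abundances that are robust to the
#' compositional nature of sequencing data. Each inference iteration draws
#' fractions from Dirichlet(counts + 1), computes the log-ratio variance
#' matrix, solves for basis variances under the sparsity approximation and
#' converts them to correlations; up to `n_exclusion` exclusion rounds each
#' remove the single strongest-correlation pair exceeding
#' `exclusion_threshold` and re-solve, so that a few strongly coupled pairs
#' do not distort the basis estimate. The final matrix is the element-wise
#' median over inference iterations.
#'
#' @param counts Counts-mode [abundance_matrix()], ideally prevalence
#'   filtered (a warning is emitted for genomes seen in under 40% of
#'   samples).
#' @param n_inference Number of Dirichlet resampling iterations (default 10).
#' @param n_exclusion Maximum exclusion rounds per iteration (default 10).
#' @param exclusion_threshold Absolute correlation above which the strongest
#'   pair is excluded from the basis system (default 0.1).
#' @param seed Integer seed; iteration `k` uses `seed + k - 1`.
#' @return Object of class `"sparcc_network"`: list with `rho` (symmetric
#'   correlation matrix, unit diagonal, entries in `[-1, 1]`), `genome_ids`,
#'   `n_inference` and `seed`.
#' @export
sparcc_correlations <- function(counts, n_inference = 10L, n_exclusion = 10L,
                                exclusion_threshold = 0.1, seed = 1L) {
  x <- unclass(counts)
  d <- nrow(x)
  if (d < 4L) stop("need at least 4 genomes; the basis solution is ",
                   "unreliable below that")
  prev <- rowMeans(x > 0)
  if (any(prev < 0.4))
    warning(sum(prev < 0.4), " genome(s) detected in <40% of samples; ",
            "consider filter_by_prevalence() first")
  rhos <- array(NA_real_, dim = c(d, d, n_inference))
  for (k in seq_len(n_inference)) {
    f <- estimate_fractions(counts, seed = as.integer(seed) + k - 1L)
    t_mat <- logratio_variance_matrix(f)
    excluded <- matrix(integer(0), ncol = 2L)
    basis <- solve_basis_variances(t_mat, excluded)
    rho <- rho_from_basis(basis$omega2, t_mat)
    for (e in seq_len(n_exclusion)) {
      a <- abs(rho)
      diag(a) <- 0
      if (nrow(excluded))
        a[rbind(excluded, excluded[, 2:1, drop = FALSE])] <- 0
      m <- max(a)
      if (m <= exclusion_threshold) break
      idx <- which(a == m, arr.ind = TRUE)[1L, ]
      pair <- sort(unname(idx))
      excluded <- rbind(excluded, pair)
      basis <- tryCatch(solve_basis_variances(t_mat, excluded),
                        error = function(err) NULL)
      if (is.null(basis)) { excluded <- excluded[-nrow(excluded), ,
                                                 drop = FALSE]; break }
      rho <- rho_from_basis(basis$omega2, t_mat)
    }
    rhos[, , k] <- rho
  }
  rho <- apply(rhos, c(1L, 2L), median)
  rho <- (rho + t(rho)) / 2
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(x), rownames(x))
  structure(list(rho = rho, genome_ids = rownames(x),
                 n_inference = as.integer(n_inference),
                 seed = as.integer(seed)),
            class = "sparcc_network")
}

#' @export
print.sparcc_network <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf(
    "sparcc_network: %d genomes, %d inference iteration(s), seed %d\n",
    length(x$genome_ids), x$n_inference, x$seed))
  cat(sprintf("  off-diagonal rho: median %.3f, range [%.3f, %.3f]\n",
              median(off), min(off), max(off)))
  invisible(x)
}
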