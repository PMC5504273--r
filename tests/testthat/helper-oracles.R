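# Independent oracles used across the suite. These deliberately use
# straight-line loops and base building blocks, not the package's internals.

# Brute-force SparCC implementation: per-sample Dirichlet draws (drawn
# column by column, matching R's column-major vectorized rgamma sequence),
# explicit pairwise log-ratio variances, the basis linear system assembled
# equation by equation, one-pair-per-round exclusions, median aggregation.
oracle_sparcc <- function(counts, n_inference = 10, n_exclusion = 10,
                          threshold = 0.1, seed = 1) {
  d <- nrow(counts); n <- ncol(counts)
  per_iter <- array(NA_real_, c(d, d, n_inference))
  for (k in seq_len(n_inference)) {
    set.seed(seed + k - 1)
    f <- matrix(0, d, n)
    for (s in seq_len(n)) {
      g <- numeric(d)
      for (i in seq_len(d)) g[i] <- rgamma(1, shape = counts[i, s] + 1)
      f[, s] <- g / sum(g)
    }
    t_mat <- matrix(0, d, d)
    for (i in seq_len(d)) for (j in seq_len(d))
      if (i != j) t_mat[i, j] <- var(log(f[i, ] / f[j, ]))
    excluded <- list()
    solve_rho <- function() {
      M <- matrix(1, d, d); diag(M) <- d - 1
      b <- rowSums(t_mat)
      for (pr in excluded) {
        i <- pr[1]; j <- pr[2]
        M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
        M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
        b[i] <- b[i] - t_mat[i, j]; b[j] <- b[j] - t_mat[i, j]
      }
      w <- solve(M, b)
      w[w <= 0] <- 1e-8
      r <- matrix(0, d, d)
      for (i in seq_len(d)) for (j in seq_len(d))
        r[i, j] <- (w[i] + w[j] - t_mat[i, j]) / (2 * sqrt(w[i] * w[j]))
      r[r > 1] <- 1; r[r < -1] <- -1; diag(r) <- 1
      r
    }
    rho <- solve_rho()
    for (e in seq_len(n_exclusion)) {
      best <- 0; best_pair <- NULL
      for (i in seq_len(d - 1)) for (j in (i + 1):d) {
        if (any(vapply(excluded, function(p) all(p == c(i, j)), TRUE)))
          next
        if (abs(rho[i, j]) > best) {
          best <- abs(rho[i, j]); best_pair <- c(i, j)
        }
      }
      if (best <= threshold) break
      excluded[[length(excluded) + 1]] <- best_pair
      rho <- solve_rho()
    }
    per_iter[, , k] <- rho
  }
  out <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    out[i, j] <- median(per_iter[i, j, ])
  diag(out) <- 1
  dimnames(out) <- list(rownames(counts), rownames(counts))
  out
}

# Benjamini-Hochberg step-up, spelled out.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- running
  }
  q
}

# Multinomial counts for independent log-normal genomes.
independent_counts <- function(d, n, depth = 20000, seed = 1, sdlog = 2) {
  set.seed(seed)
  lat <- matrix(rlnorm(d * n, 0, sdlog), d, n)
  frac <- sweep(lat, 2, colSums(lat), "/")
  cnt <- vapply(seq_len(n), function(s)
    rmultinom(1, depth, frac[, s])[, 1], integer(d))
  dimnames(cnt) <- list(paste0("g", seq_len(d)), paste0("s", seq_len(n)))
  cnt
}

# Counts with two exactly proportional genomes appended to independents.
proportional_pair_counts <- function(d_indep = 10, n = 200, depth = 20000,
                                     seed = 1) {
  set.seed(seed)
  lat <- matrix(rlnorm(d_indep * n, 0, 2), d_indep, n)
  lat <- rbind(lat, lat[1, ] * 0, lat[1, ] * 0)  # placeholders
  base <- rlnorm(n, 0, 2)
  lat[d_indep + 1, ] <- base
  lat[d_indep + 2, ] <- 2 * base
  frac <- sweep(lat, 2, colSums(lat), "/")
  cnt <- vapply(seq_len(n), function(s)
    rmultinom(1, depth, frac[, s])[, 1], integer(d_indep + 2))
  dimnames(cnt) <- list(paste0("g", seq_len(d_indep + 2)),
                        paste0("s", seq_len(n)))
  cnt
}

# Split a synthetic community's viruses into labelled references and
# unlabelled queries: the first `refs_per_host` viruses of each host are
# references.
reference_host_table <- function(com, refs_per_host = 2) {
  truth <- com$virus_truth
  idx <- unlist(lapply(split(seq_len(nrow(truth)), truth$host_id),
                       utils::head, refs_per_host), use.names = FALSE)
  ref <- truth[idx, ]
  cbind(data.frame(genome_id = ref$virus_id, stringsAsFactors = FALSE),
        com$host_taxa[match(ref$host_id, com$host_taxa$genome_id),
                      taxonomic_ranks()],
        row.names = NULL)
}

# Host taxonomy rows for a handful of named genomes.
toy_hosts <- function() {
  data.frame(
    genome_id = c("RefA", "RefB", "RefC", "RefD"),
    domain = "Bacteria",
    phylum = c("Cyanobacteria", "Cyanobacteria", "Proteobacteria",
               "Proteobacteria"),
    class = c("Cyanophyceae", "Cyanophyceae", "Alphaproteobacteria",
              "Alphaproteobacteria"),
    order = c("Synechococcales", "Synechococcales", "Pelagibacterales",
              "Pelagibacterales"),
    family = c("Prochloraceae", "Prochloraceae", "Pelagibacteraceae",
               "Pelagibacteraceae"),
    genus = c("Prochlorococcus", "Prochlorococcus", "Pelagibacter",
              "Puniceispirillum"),
    species = NA_character_, stringsAsFactors = FALSE)
}

# A correlation network built directly from a named square matrix.
toy_network <- function(rho) {
  structure(list(rho = rho, genome_ids = rownames(rho)),
            class = "sparcc_network")
}

sym_rho <- function(ids, fill = 0) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

set_rho <- function(m, a, b, v) {
  m[a, b] <- v; m[b, a] <- v
  m
}
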