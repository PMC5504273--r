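#' Simulate a virus-host community with known coupling
#'
#' Generates the ground-truth substrate for validating the whole toolkit:
#' host taxa with log-normal abundance dynamics across samples, viruses
#' whose latent abundance tracks their true host's abundance with a
#' controllable `coupling`, and virome read counts drawn multinomially at a
#' fixed sequencing depth per sample. Each virus's latent abundance is
#' `coupling * host_abundance + (1 - coupling) * noise` with log-normal
#' noise of the given `dispersion`, so `coupling = 1` with vanishing
#' dispersion makes every virus exactly proportional to its host and
#' `coupling = 0` decouples them entirely.
#'
#' Hosts get distinct genera, grouped into phyla (`genera_per_phylum` per
#' phylum), with intermediate ranks filled so every lineage is a contiguous
#' domain-to-genus chain.
#'
#' @param n_hosts Number of host taxa (default 20).
#' @param viruses_per_host Viruses infecting each host (default 3).
#' @param n_samples Number of samples (default 120).
#' @param coupling Virus-host coupling in `[0, 1]` (default 0.95).
#' @param dispersion Standard deviation of the log-normal virus noise
#'   (default 1).
#' @param depth Sequencing depth (reads per sample, default 1e5).
#' @param seed Integer seed; the same seed reproduces the community.
#' @param sigma_host Standard deviation of host log-abundance across
#'   samples (default 2, a heavy-tailed dynamic range typical of marine
#'   communities).
#' @param genera_per_phylum Host genera per synthetic phylum (default 4).
#' @return List of class `"synthetic_community"`: `host_taxa` (taxonomy
#'   data frame for the hosts), `host_abundance` (taxa x samples, relative),
#'   `virus_truth` (`virus_id`, `host_id`, `genus`, `phylum`),
#'   `virus_counts` (viruses x samples integer matrix), `virus_fractions`
#'   (the latent relative abundances), and the parameters.
#' @export
simulate_community <- function(n_hosts = 20L, viruses_per_host = 3L,
                               n_samples = 120L, coupling = 0.95,
                               dispersion = 1, depth = 1e5L, seed = 1L,
                               sigma_host = 2, genera_per_phylum = 4L) {
  stopifnot(n_hosts >= 1, viruses_per_host >= 1, n_samples >= 1,
            coupling >= 0, coupling <= 1, dispersion > 0, depth >= 1)
  if (depth < 10 * n_hosts * viruses_per_host)
    warning("sequencing depth is small relative to the number of viruses; ",
            "some may go undetected")
  set.seed(as.integer(seed))
  hosts <- sprintf("Host_%02d", seq_len(n_hosts))
  samples <- sprintf("S%03d", seq_len(n_samples))
  phyl_idx <- (seq_len(n_hosts) - 1L) %/% genera_per_phylum + 1L
  host_taxa <- data.frame(
    genome_id = hosts,
    domain = "Bacteria",
    phylum = sprintf("Phylum_%02d", phyl_idx),
    class = sprintf("Class_%02d", phyl_idx),
    order = sprintf("Order_%02d", seq_len(n_hosts)),
    family = sprintf("Family_%02d", seq_len(n_hosts)),
    genus = sprintf("Genus_%02d", seq_len(n_hosts)),
    species = NA_character_, stringsAsFactors = FALSE)

  host_lat <- matrix(rlnorm(n_hosts * n_samples, 0, sigma_host),
                     n_hosts, n_samples, dimnames = list(hosts, samples))
  host_rel <- sweep(host_lat, 2L, colSums(host_lat), "/")

  n_vir <- n_hosts * viruses_per_host
  viruses <- sprintf("MVC_%03d", seq_len(n_vir))
  vhost <- rep(seq_len(n_hosts), each = viruses_per_host)
  noise <- matrix(rlnorm(n_vir * n_samples, 0, dispersion),
                  n_vir, n_samples)
  vir_lat <- coupling * host_lat[vhost, , drop = FALSE] +
    (1 - coupling) * noise
  dimnames(vir_lat) <- list(viruses, samples)
  vir_frac <- sweep(vir_lat, 2L, colSums(vir_lat), "/")

  counts <- vapply(seq_len(n_samples), function(s)
    rmultinom(1L, size = as.integer(depth), prob = vir_frac[, s])[, 1L],
    integer(n_vir))
  dimnames(counts) <- list(viruses, samples)

  structure(list(
    host_taxa = host_taxa,
    host_abundance = host_rel,
    virus_truth = data.frame(
      virus_id = viruses, host_id = hosts[vhost],
      genus = host_taxa$genus[vhost], phylum = host_taxa$phylum[vhost],
      stringsAsFactors = FALSE),
    virus_counts = counts,
    virus_fractions = vir_frac,
    coupling = coupling, dispersion = dispersion,
    depth = as.integer(depth), seed = as.integer(seed)),
    class = "synthetic_community")
}

#' Simulate an all-vs-all homology hit table with group structure
#'
#' Emits a hit table in the tabular alignment dialect for `n_groups`
#' groups of genomes, where within-group cross-hits carry a larger summed
#' bitscore than between-group ones, self-hits are always present with the
#' maximal score, and a sprinkle of sub-threshold hits (low identity, short
#' length, high e-value) exercises the homology filters. The expected Dice
#' distance is therefore smaller within groups than between them.
#'
#' @param n_groups Number of genome groups (>= 2 for a meaningful
#'   between-group contrast; 1 is allowed).
#' @param genomes_per_group Genomes per group (default 4).
#' @param seed Integer seed.
#' @param self_score Summed self-hit bitscore per genome (default 4000).
#' @param within_frac,between_frac Expected cross-score as a fraction of
#'   the self score within and between groups (defaults 0.6 and 0.05).
#' @return List with `hits` (the hit table) and `truth` (data frame
#'   `genome_id`, `group`).
#' @export
simulate_homology_set <- function(n_groups, genomes_per_group = 4L,
                                  seed = 1L, self_score = 4000,
                                  within_frac = 0.6, between_frac = 0.05) {
  stopifnot(n_groups >= 1, genomes_per_group >= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("G%02d_%02d", rep(seq_len(n_groups),
                                   each = genomes_per_group),
                 rep(seq_len(genomes_per_group), n_groups))
  grp <- rep(seq_len(n_groups), each = genomes_per_group)
  rows <- list()
  add_hit <- function(q, s, bits, id = 80, len = 150, e = 1e-30) {
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = q, subject_id = s, percent_identity = id,
      alignment_length = len, mismatches = 10L, gaps = 0L,
      e_value = e, bitscore = bits, stringsAsFactors = FALSE)
  }
  for (i in seq_along(ids)) {
    add_hit(ids[i], ids[i], self_score)
    for (j in seq_along(ids)) {
      if (i == j) next
      frac <- if (grp[i] == grp[j]) within_frac else between_frac
      bits <- self_score * frac * runif(1, 0.8, 1.2)
      add_hit(ids[i], ids[j], bits)
      # a junk hit failing each filter in turn, to be ignored downstream
      if (runif(1) < 0.3)
        add_hit(ids[i], ids[j], 50,
                id = sample(c(20, 80, 80), 1L),
                len = sample(c(150, 20, 150), 1L),
                e = sample(c(1e-30, 1e-30, 0.5), 1L))
    }
  }
  list(hits = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = data.frame(genome_id = ids, group = grp,
                          stringsAsFactors = FALSE))
}

#' Simulate a read alignment table from a synthetic community
#'
#' Draws per-sample reads from the community's latent virus fractions and
#' emits the long alignment table consumed by [assign_reads()]. A stated
#' fraction of reads is made ambiguous: each such read also aligns to a
#' second genome chosen with probability proportional to abundance in that
#' sample. The per-genome read origin is retained as truth.
#'
#' @param community A `"synthetic_community"` from [simulate_community()].
#' @param ambiguous_fraction Fraction of reads given a second alignment,
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @param depth Reads per sample (default: the community's depth).
#' @param samples Sample ids to simulate (default: first 3, to keep tables
#'   small; pass all for full-scale tables).
#' @return List with `alignments` (data frame `read_id`, `genome_id`,
#'   `sample_id`) and `truth_counts` (true origin counts, genomes x
#'   samples).
#' @export
simulate_read_alignments <- function(community, ambiguous_fraction = 0.1,
                                     seed = 1L, depth = NULL,
                                     samples = NULL) {
  stopifnot(ambiguous_fraction >= 0, ambiguous_fraction < 1)
  set.seed(as.integer(seed))
  frac <- community$virus_fractions
  if (is.null(samples)) samples <- colnames(frac)[seq_len(min(3L,
                                                        ncol(frac)))]
  if (is.null(depth)) depth <- community$depth
  genomes <- rownames(frac)
  truth <- matrix(0L, length(genomes), length(samples),
                  dimnames = list(genomes, samples))
  rows <- list()
  for (s in samples) {
    origin <- sample(genomes, depth, replace = TRUE, prob = frac[, s])
    tab <- table(factor(origin, levels = genomes))
    truth[, s] <- as.integer(tab)
    read_ids <- sprintf("%s_r%06d", s, seq_len(depth))
    amb <- runif(depth) < ambiguous_fraction
    second <- rep(NA_character_, depth)
    if (any(amb)) {
      second[amb] <- sample(genomes, sum(amb), replace = TRUE,
                            prob = frac[, s])
      clash <- amb & second == origin
      while (any(clash)) {   # resample until the second genome differs
        second[clash] <- sample(genomes, sum(clash), replace = TRUE,
                                prob = frac[, s])
        clash <- amb & second == origin
      }
    }
    rows[[s]] <- data.frame(
      read_id = c(read_ids, read_ids[amb]),
      genome_id = c(origin, second[amb]),
      sample_id = s, stringsAsFactors = FALSE)
  }
  list(alignments = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth_counts = truth)
}

#' Simulate virus/host-ratio records with a power-law host dependence
#'
#' Generates VHR records where `vhr = host^(-gamma) * noise`, the
#' functional form under which stronger lysogeny at high host density
#' (`gamma > 0`) yields a negative host-abundance-VHR correlation, while
#' `gamma = 0` makes VHR independent of host abundance.
#'
#' @param n Number of records (default 100).
#' @param gamma Power-law exponent (>= 0).
#' @param noise_sd Standard deviation of log-normal noise (default 0.5).
#' @param seed Integer seed.
#' @return VHR record data frame as accepted by [vhr_association()].
#' @export
simulate_vhr_records <- function(n = 100L, gamma = 0.5, noise_sd = 0.5,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  host <- rlnorm(n, meanlog = -4, sdlog = 1.5)
  vhr <- host^(-gamma) * rlnorm(n, 0, noise_sd)
  data.frame(taxon = "Taxon_pooled", rank = "genus",
             sample_id = sprintf("S%03d", seq_len(n)),
             host_abundance = host, viral_abundance = vhr * host,
             vhr = vhr, defined = TRUE, stringsAsFactors = FALSE)
}
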