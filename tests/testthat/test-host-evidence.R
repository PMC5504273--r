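hit_row <- function(query = "Q1", subject = "RefA", pident = 85,
                    len = 1200, mism = 10, gaps = 0, e = 1e-50,
                    bits = 1000, ...) {
  data.frame(query_id = query, subject_id = subject,
             percent_identity = pident, alignment_length = len,
             mismatches = mism, gaps = gaps, e_value = e, bitscore = bits,
             ..., stringsAsFactors = FALSE)
}

test_that("genome homology requires >80% identity over >=1000 nt", {
  hosts <- toy_hosts()
  expect_equal(nrow(host_by_genome_homology(hit_row(pident = 85,
                                                    len = 1200), hosts)), 1)
  expect_equal(nrow(host_by_genome_homology(hit_row(pident = 85,
                                                    len = 900), hosts)), 0)
  # identity bound is strict, length bound inclusive
  expect_equal(nrow(host_by_genome_homology(hit_row(pident = 80,
                                                    len = 1200), hosts)), 0)
  expect_equal(nrow(host_by_genome_homology(hit_row(pident = 80.1,
                                                    len = 1000), hosts)), 1)
})

test_that("genome homology keeps the highest-bitscore qualifying hit", {
  hosts <- toy_hosts()
  hits <- rbind(hit_row(subject = "RefC", bits = 1500),
                hit_row(subject = "RefA", bits = 900))
  res <- host_by_genome_homology(hits, hosts)
  expect_equal(res$taxon, "Pelagibacter")
  expect_equal(res$score, 1500)
  # subjects without taxonomy are skipped with a warning
  expect_warning(
    none <- host_by_genome_homology(hit_row(subject = "Unknown"), hosts),
    "skipped")
  expect_equal(nrow(none), 0)
})

prot_hits <- function(taxa_bits, contig = "C1", genus_col = TRUE) {
  # taxa_bits: named numeric, genus -> bitscore; one protein per hit
  n <- length(taxa_bits)
  data.frame(contig_id = contig, protein_id = sprintf("p%02d", seq_len(n)),
             bitscore = unname(taxa_bits), e_value = 1e-20,
             percent_identity = 60, domain = "Bacteria",
             phylum = "Cyanobacteria", class = "Cyanophyceae",
             order = "Synechococcales", family = "Prochloraceae",
             genus = names(taxa_bits), species = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("bitscore voting classifies at 80% consistency over total >= 1000", {
  h <- prot_hits(c(Prochlorococcus = 900, Synechococcus = 200))
  res <- classify_contig_taxonomy(h)
  expect_equal(res$status, "classified")
  expect_equal(res$genus, "Prochlorococcus")   # 900/1100 = 81.8% >= 80%
  expect_equal(res$classified_rank, "genus")

  # below the total-bitscore floor: unclassified
  low <- classify_contig_taxonomy(prot_hits(c(Prochlorococcus = 900)))
  expect_equal(low$status, "unclassified")
  expect_true(is.na(low$genus))

  # an even genus split still fixes the shared upper ranks
  split <- prot_hits(c(Prochlorococcus = 600, Synechococcus = 600))
  res2 <- classify_contig_taxonomy(split)
  expect_equal(res2$classified_rank, "family")
  expect_true(is.na(res2$genus))
  expect_equal(res2$phylum, "Cyanobacteria")
})

test_that("voting respects the e-value/identity prefilter and discards", {
  # non-prokaryotic domains
  h <- prot_hits(c(Prochlorococcus = 2000))
  h$e_value <- 1e-3                      # fails e < 1e-5
  expect_equal(nrow(classify_contig_taxonomy(h)), 0)
  h2 <- prot_hits(c(Prochlorococcus = 2000))
  h2$percent_identity <- 25              # fails identity > 30
  expect_equal(nrow(classify_contig_taxonomy(h2)), 0)
  viral <- prot_hits(c(Prochlorococcus = 2000))
  viral$domain <- "Viruses"
  expect_equal(classify_contig_taxonomy(viral)$status, "discarded")
})

spacer_hit <- function(mism = 0, gaps = 0, alen = 28, slen = 28,
                       spacer = "sp1", contig = "C1") {
  data.frame(query_id = spacer, subject_id = contig,
             percent_identity = 100, alignment_length = alen,
             mismatches = mism, gaps = gaps, e_value = 1e-6,
             bitscore = 50, spacer_length = slen, stringsAsFactors = FALSE)
}

test_that("CRISPR matches allow at most two mismatches/gaps, full length", {
  sources <- data.frame(spacer_id = c("sp1", "sp2"),
                        source_genome_id = c("RefA", "RefC"),
                        stringsAsFactors = FALSE)
  hosts <- toy_hosts()
  ok <- host_by_crispr(spacer_hit(mism = 2), sources, hosts)
  expect_equal(ok$taxon, "Prochlorococcus")
  expect_equal(nrow(host_by_crispr(spacer_hit(mism = 3), sources, hosts)), 0)
  expect_equal(nrow(host_by_crispr(spacer_hit(mism = 1, gaps = 2),
                                   sources, hosts)), 0)
  # partial spacer coverage is rejected
  expect_equal(nrow(host_by_crispr(spacer_hit(alen = 24), sources, hosts)),
               0)
  # a gap shortens the allowed alignment accordingly
  expect_equal(nrow(host_by_crispr(spacer_hit(gaps = 1, alen = 27),
                                   sources, hosts)), 1)
  exact <- host_by_crispr(spacer_hit(), sources, hosts)
  expect_match(exact$support, "1 spacer")
  expect_false(exact$conflict)
  expect_error(host_by_crispr(spacer_hit()[-9], sources, hosts),
               "spacer_length")
})

test_that("conflicting CRISPR phyla are all reported and flagged", {
  sources <- data.frame(spacer_id = c("sp1", "sp2"),
                        source_genome_id = c("RefA", "RefC"),
                        stringsAsFactors = FALSE)
  hits <- rbind(spacer_hit(spacer = "sp1"), spacer_hit(spacer = "sp2"))
  expect_warning(res <- host_by_crispr(hits, sources, toy_hosts()),
                 "multiple phyla")
  expect_equal(nrow(res), 2)
  expect_true(all(res$conflict))
})

trna_hit <- function(pident = 95, cov = 0.95, subject = "RefA",
                     bits = 100, e = 1e-20) {
  data.frame(query_id = "C1_tRNA1", subject_id = subject,
             percent_identity = pident, alignment_length = 75,
             mismatches = 2, gaps = 0, e_value = e, bitscore = bits,
             subject_coverage = cov, contig_id = "C1",
             stringsAsFactors = FALSE)
}

test_that("tRNA matches require 90% identity and 90% coverage", {
  hosts <- toy_hosts()
  expect_equal(host_by_trna(trna_hit(95, 0.95), hosts)$taxon,
               "Prochlorococcus")
  expect_equal(nrow(host_by_trna(trna_hit(95, 0.80), hosts)), 0)
  expect_equal(nrow(host_by_trna(trna_hit(85, 0.95), hosts)), 0)
  # both bounds inclusive
  expect_equal(nrow(host_by_trna(trna_hit(90, 0.9), hosts)), 1)
  expect_error(host_by_trna(trna_hit()[-9], hosts), "subject_coverage")
  # bitscore tie broken deterministically (lower e-value wins)
  hits <- rbind(trna_hit(subject = "RefB", e = 1e-30),
                trna_hit(subject = "RefA", e = 1e-10))
  expect_match(host_by_trna(hits, hosts)$support, "RefB")
})

test_that("tightening a threshold never adds an assignment", {
  set.seed(71)
  hosts <- toy_hosts()
  hits <- do.call(rbind, lapply(1:60, function(i)
    hit_row(query = sample(sprintf("Q%d", 1:10), 1),
            subject = sample(hosts$genome_id, 1),
            pident = runif(1, 60, 100),
            len = sample(500:2000, 1), bits = runif(1, 200, 2000))))
  loose <- host_by_genome_homology(hits, hosts, min_identity = 70,
                                   min_length = 800)
  tight <- host_by_genome_homology(hits, hosts, min_identity = 85,
                                   min_length = 1200)
  expect_true(all(tight$query_id %in% loose$query_id))
})

test_that("consolidation counts methods independently per taxon", {
  hosts <- toy_hosts()
  ids <- c("RefC", "Q1", "Q2", "Q3")
  rho <- sym_rho(ids)
  for (q in c("Q1", "Q2", "Q3")) rho <- set_rho(rho, q, "RefC", 0.9)
  net_pred <- predict_hosts(toy_network(rho), hosts, rank = "genus",
                            cutoff = 0.6)
  cons <- consolidate_predictions(net_pred)
  pel <- cons$summary[cons$summary$taxon == "Pelagibacter", ]
  expect_equal(unlist(pel[c("refseq_homology", "tara_homology", "crispr",
                            "trna", "network")], use.names = FALSE),
               c(0, 0, 0, 0, 3))

  # a query assigned by two methods to different taxa counts in both
  hom <- host_by_genome_homology(hit_row(query = "Q1", subject = "RefA"),
                                 hosts)
  both <- consolidate_predictions(net_pred, hom)$summary
  expect_equal(both$network[both$taxon == "Pelagibacter"], 3)
  expect_equal(both$refseq_homology[both$taxon == "Prochlorococcus"], 1)

  empty <- consolidate_predictions(list())
  expect_equal(nrow(empty$summary), 0)
})
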