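tblastx_hit <- function(q, s, pident = 50, len = 100, e = 1e-10,
                        bits = 500) {
  data.frame(query_id = q, subject_id = s, percent_identity = pident,
             alignment_length = len, mismatches = 0L, gaps = 0L,
             e_value = e, bitscore = bits, stringsAsFactors = FALSE)
}

test_that("homology hits are filtered at 30% identity, 30 aa, e 0.01", {
  hits <- rbind(
    tblastx_hit("A", "A"), tblastx_hit("B", "B"),
    tblastx_hit("A", "B", pident = 25),              # identity fails
    tblastx_hit("A", "B", pident = 40, len = 35, e = 0.005),  # passes
    tblastx_hit("A", "B", pident = 40, len = 29),    # length fails
    tblastx_hit("A", "B", e = 0.02),                 # e-value fails
    tblastx_hit("A", "B", pident = 30, len = 30, e = 0.01))  # boundary in
  out <- filter_homology_hits(hits)
  ab <- out[out$query_id == "A" & out$subject_id == "B", ]
  expect_equal(nrow(ab), 2)
  expect_true(all(ab$percent_identity >= 30))
})

test_that("genomes losing their self-hits are warned and dropped", {
  hits <- rbind(tblastx_hit("A", "A"),
                tblastx_hit("B", "B", pident = 10),  # self-hit filtered out
                tblastx_hit("A", "B"), tblastx_hit("B", "A"))
  expect_warning(f <- filter_homology_hits(hits), "self-hits")
  expect_warning(sim <- genome_similarity(f), "dropping")
  expect_equal(sim$ids, "A")
})

test_that("Dice distances follow the summed-bitscore formula", {
  hits <- rbind(tblastx_hit("A", "A", bits = 100),
                tblastx_hit("B", "B", bits = 300),
                tblastx_hit("A", "B", bits = 100),
                tblastx_hit("B", "A", bits = 100))
  D <- dice_distance_matrix(genome_similarity(hits))
  expect_equal(D$D["A", "B"], 1 - 200 / 400)   # = 0.5
  expect_equal(D$D["A", "A"], 0)

  # no cross-hits: distance 1
  disjoint <- rbind(tblastx_hit("A", "A", bits = 100),
                    tblastx_hit("B", "B", bits = 100))
  expect_equal(dice_distance_matrix(genome_similarity(disjoint))$D["A", "B"],
               1)
  # multiple self-hits are summed
  multi <- rbind(tblastx_hit("A", "A", bits = 60),
                 tblastx_hit("A", "A", bits = 40) |>
                   transform(alignment_length = 90),
                 tblastx_hit("B", "B", bits = 300),
                 tblastx_hit("A", "B", bits = 100),
                 tblastx_hit("B", "A", bits = 100))
  expect_equal(dice_distance_matrix(genome_similarity(multi))$D["A", "B"],
               0.5)
})

test_that("asymmetric searches still give a symmetric distance matrix", {
  hits <- rbind(tblastx_hit("A", "A", bits = 200),
                tblastx_hit("B", "B", bits = 200),
                tblastx_hit("A", "B", bits = 150),
                tblastx_hit("B", "A", bits = 50))
  D <- dice_distance_matrix(genome_similarity(hits))$D
  expect_equal(D, t(D))
  expect_equal(D["A", "B"], 1 - 2 * 100 / 400)
})

test_that("increasing cross-hit bitscore decreases the distance", {
  base <- rbind(tblastx_hit("A", "A", bits = 400),
                tblastx_hit("B", "B", bits = 400),
                tblastx_hit("A", "B", bits = 100),
                tblastx_hit("B", "A", bits = 100))
  more <- base
  more$bitscore[3:4] <- more$bitscore[3:4] + 50
  d1 <- dice_distance_matrix(genome_similarity(base))$D["A", "B"]
  d2 <- dice_distance_matrix(genome_similarity(more))$D["A", "B"]
  expect_lt(d2, d1)
})

test_that("three-taxon BIONJ branch lengths match the closed form", {
  ids <- c("A", "B", "C")
  D <- sym_rho(ids, 0); diag(D) <- 0
  D["A", "B"] <- D["B", "A"] <- 0.2
  D["A", "C"] <- D["C", "A"] <- 0.3
  D["B", "C"] <- D["C", "B"] <- 0.4
  tr <- bionj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.05)   # (0.2 + 0.3 - 0.4) / 2
  expect_equal(bl[["B"]], 0.15)
  expect_equal(bl[["C"]], 0.25)
})

test_that("additive distances are recovered exactly, matching plain NJ", {
  set.seed(81)
  for (rep in 1:5) {
    ref <- ape::rtree(5, br = function(n) runif(n, 0.1, 1))
    D <- ape::cophenetic.phylo(ref)
    D <- (D + t(D)) / 2
    tr <- bionj_tree(D)
    rec <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(rec - D)), 1e-9)
    nj <- ape::nj(D)   # independent plain-NJ oracle
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
                 ignore_attr = TRUE)
    njd <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
    expect_lt(max(abs(njd - rec)), 1e-9)
  }
})

test_that("malformed distance matrices are rejected", {
  ids <- c("A", "B", "C")
  D <- sym_rho(ids, 0.5); diag(D) <- 0
  bad <- D; bad["A", "B"] <- 0.9
  expect_error(bionj_tree(bad), "symmetric")
  nan <- D; nan["A", "B"] <- nan["B", "A"] <- NaN
  expect_error(bionj_tree(nan), "NA/NaN")
  expect_error(bionj_tree(D[1:2, 1:2]), "3 taxa")
})

test_that("equal pairwise distances give a star-like tree", {
  ids <- paste0("T", 1:4)
  D <- matrix(0.6, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  tr <- bionj_tree(D)
  term <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(term, rep(0.3, 4))
  expect_s3_class(tr, "phylo")
  expect_true(grepl(";$", ape::write.tree(tr)))
})

test_that("cluster extraction respects the diameter bound", {
  # two tight 3-leaf clades separated by a long internal branch
  tr <- ape::read.tree(text =
    "((a1:0.05,(a2:0.05,a3:0.05):0.02):5,(b1:0.05,(b2:0.05,b3:0.05):0.02):5);")
  cl <- extract_clusters(tr, max_depth = 1)
  expect_equal(length(cl), 2)
  expect_setequal(cl[[which(vapply(cl, function(x) "a1" %in% x, TRUE))]],
                  c("a1", "a2", "a3"))

  expect_equal(length(extract_clusters(tr, Inf)), 1)
  expect_equal(length(extract_clusters(tr, 0)), 6)
  expect_error(extract_clusters(tr, -1), "non-negative")

  comp <- cluster_composition(cl, novel_ids = c("a1", "a2", "a3"))
  expect_equal(sort(comp$fraction_novel), c(0, 1))
})

test_that("simulated homology groups are recovered end to end", {
  hs <- simulate_homology_set(2, genomes_per_group = 4, seed = 9)
  D <- dice_distance_matrix(genome_similarity(
    suppressWarnings(filter_homology_hits(hs$hits))))
  within <- D$D[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
  between <- D$D[1:4, 5:8]
  expect_lt(max(within), min(between))
  tr <- bionj_tree(D)
  cl <- extract_clusters(tr, max_depth = max(within) + 0.05)
  grp_of <- setNames(hs$truth$group, hs$truth$genome_id)
  expect_true(all(vapply(cl, function(x)
    length(unique(grp_of[x])) == 1, TRUE)))
})
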