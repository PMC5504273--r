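---
title: "Methods: co-occurrence networks, host prediction and comparative genomics for viromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, host prediction and comparative genomics for viromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

viromenet analyses collections of assembled viral genomes (contigs) across
many virome samples. This vignette explains the models and procedures the
package implements, the parameters that matter, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Abundance profiles from read alignments

`assign_reads()` turns read-to-genome alignments into a genome × sample
count matrix. Within a sample, a read aligning to exactly one genome
contributes 1.0 to it. A read aligning ambiguously to genomes
$g_1,\dots,g_k$ is split by the unambiguous evidence:

$$w_i = \frac{u_i}{\sum_j u_j},$$

where $u_i$ is the sample's count of unambiguous reads assigned to $g_i$.
This is a single pass — unique counts first, then one allocation of
ambiguous reads — not an EM iteration; the one-pass weighting is the
simplest scheme that uses the unambiguous evidence and keeps the result
independent of the order in which reads are processed.

Open choices and how they were resolved:

* **All candidates have zero unique reads.** The read is split evenly,
  $1/k$ each. Any other rule would either discard the read (breaking the
  conservation property below) or inject information that is not in the
  data.
* **Conservation.** The total weight assigned per sample equals the number
  of distinct mapped reads, up to floating-point accumulation (the suite
  asserts it at $10^{-12}$ relative tolerance).
* **Known bias.** Ratio-based reassignment leaks a little mass from rare
  genomes toward abundant ones when ambiguity is itself
  abundance-correlated; with 10% ambiguous reads at depth $10^5$ the
  per-genome relative error stays within a few percent (asserted in the
  suite at 10%).
* **No genome-length normalization.** Counts are per genome, not per
  kilobase. Length normalization cancels from SparCC (which works on
  log-ratios across samples, and a genome's length is constant across
  samples) and from any per-genome cross-sample comparison; it matters only
  if abundances of *different* genomes are compared directly. It is
  deliberately not applied; callers comparing across genomes should divide
  by length themselves.

`to_relative()` divides each sample column by its sum (all-zero columns are
preserved and warned about). `filter_by_prevalence()` removes genomes
detected — strictly positive abundance, any weight counts — in fewer than
40% of samples by default; sparse features are a classic source of spurious
compositional correlations, and every downstream network analysis assumes
this filter has been applied.

## Compositionally robust correlations (SparCC-style)

Sequencing data are compositional: only relative information survives
library normalization, so naive Pearson correlations between relative
abundances are biased (a genome that blooms forces every other fraction
down). The package implements the log-ratio variance approach:

1. **Fractions.** Per inference iteration, per sample, fractions are drawn
   from Dirichlet(counts + 1) (`estimate_fractions()`). The +1 pseudocount
   makes zero counts usable and the resampling propagates count
   uncertainty.
2. **Log-ratio variances.** $t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$ across
   samples (`logratio_variance_matrix()`). $t$ is computed from the
   covariance matrix of log-fractions, $t_{ij} = V_{ii} + V_{jj} - 2V_{ij}$,
   with tiny negative values (numerical noise on near-proportional pairs)
   clamped to zero.
3. **Basis variances.** Writing $t_{ij} = \omega_i^2 + \omega_j^2 -
   2\rho_{ij}\omega_i\omega_j$ and assuming most pairs are uncorrelated
   (sparsity), row sums give the linear system
   $\sum_j t_{ij} \approx (d-1)\,\omega_i^2 + \sum_{j\neq i}\omega_j^2$,
   solved directly (`solve_basis_variances()`). Non-positive solutions are
   clamped to $10^{-8}$ and warned about.
4. **Exclusions.** Strongly correlated pairs violate the sparsity
   assumption, so up to 10 exclusion rounds each remove the single
   strongest pair with $|\rho|$ above 0.1 from the system and re-solve.
5. **Aggregation.** $\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) /
   (2\omega_i\omega_j)$, clamped to $[-1,1]$; the final matrix is the
   element-wise **median** over 10 inference iterations (robust to outlier
   Dirichlet draws), symmetrized, unit diagonal.

Defaults (10 inference iterations, 10 exclusion rounds, exclusion threshold
0.1, pseudocount 1) follow the established reference procedure for this
estimator. The implementation requires at least 4 genomes (the basis system
is unreliable below that) and at least 3 samples. Counts — not relative
abundances — are the expected input; the Dirichlet step needs integers.

The test suite cross-checks the whole chain against an independent
brute-force implementation of the same equations (explicit loops, no shared
code) and verifies the compositional robustness directly: multiplying any
sample's counts by a constant moves no correlation by more than 0.05.

## Host prediction from the co-occurrence network

Viruses infecting the same host compete for it, so their abundances track
the host's and therefore each other across samples. `predict_hosts()`
assigns a query virus (no known host) the host of the reference virus
(known host) with which it has the strongest positive correlation, provided
$\rho \ge$ the cutoff (default +0.6).

* **Cutoff.** `evaluate_reference_accuracy()` calibrates it: each labelled
  reference is predicted leave-self-out from the remaining references and
  scored at a chosen rank, over a cutoff grid. Raising the cutoff trades
  coverage (monotonically fewer predictions — an invariant the suite
  checks) for precision. The +0.6 default is the knee the calibration curve
  shows on separable data.
* **Ties.** Ties at the maximum correlation assign only when every tied
  reference agrees at the requested rank; otherwise the query abstains and
  is logged. Abstention preserves measured precision at the cost of
  coverage.
* **Negative correlations** are never used for prediction — competitive
  exclusion can produce them between same-host viruses, but they are rare
  and their sign is not evidence of a shared host.
  `same_host_correlation_census()` quantifies exactly this: among labelled
  reference pairs sharing a taxon, it counts positive versus negative
  correlations, excluding $|\rho| < 0.3$ as too close to zero for a
  reliable sign call.
* **Missing ranks** fall back to the deepest available rank of the
  reference's lineage, flagged in the `support` field.
* Accuracy where nothing is predicted is reported as `NA`, never 0 or 1.

## Alignment-evidence host prediction

Four deterministic filters over precomputed hit tables complement the
network method. "Best hit" always means maximum bitscore, ties broken by
lower e-value and then lexicographic subject id, so outputs are
reproducible. Boundary semantics, exercised one by one in the suite:

| filter | thresholds | boundary |
|---|---|---|
| genome homology (`host_by_genome_homology`) | identity > 80%, length ≥ 1000 nt | identity strict, length inclusive |
| contig taxonomy (`classify_contig_taxonomy`) | e < 1e-5, identity > 30 prefilter; total bitscore ≥ 1000; 80% bitscore share per rank | share threshold inclusive |
| CRISPR spacers (`host_by_crispr`) | mismatches + gaps ≤ 2; full spacer coverage | alignment ≥ spacer length − gaps |
| tRNA matches (`host_by_trna`) | identity ≥ 90%, query coverage ≥ 90% | both inclusive |

The contig-taxonomy voter descends domain → species, fixing a taxon at each
rank while it holds at least 80% of the contig's **post-filter** total
bitscore (the denominator choice that makes the per-rank share
non-increasing with depth), stops at the first rank where no taxon reaches
the threshold, and discards contigs resolving to viral or eukaryotic
domains or unclassifiable at domain. CRISPR spacers are ~20–30 nt, so full
spacer coverage is required on top of the mismatch budget — partial matches
of sequences that short are noise. Conflicting spacer evidence (different
phyla) is reported in full and flagged rather than resolved silently.

`consolidate_predictions()` tabulates assignments per taxon × method,
counting methods independently — the methods are complementary lines of
evidence, not votes to be merged.

## Dice-distance phylogenomics

Genome relatedness is summarized from an all-vs-all translated search
without alignments, marker genes or orthology calls. After filtering hits
(identity ≥ 30%, length ≥ 30 aa, e ≤ 0.01), summed bitscores give

$$D_{A,B} = 1 - \frac{2\,AB}{AA + BB}$$

with $AA$, $BB$ the summed self-scores and $AB$ the cross-score. Two
interpretation choices are deliberate: the formula is parenthesized as
$2\,AB/(AA+BB)$ — the only reading with $D_{A,A}=0$ and $D \in [0,1]$ — and
the directional cross-scores are symmetrized, $AB_{sym} = (S_{AB} +
S_{BA})/2$, which reduces to $AB$ for a symmetric search. Self-scores sum
*all* qualifying self-hits (a genome with internally repeated proteins
simply has a larger $AA$ and $BB$ in equal measure). Pairs with no
qualifying cross-hit sit at distance 1 and are retained rather than
dropped; callers wanting the "at least one homologue" restriction can
filter on that themselves.

`bionj_tree()` clusters the distance matrix with the BIONJ variant of
neighbor joining: the standard Q-criterion pair selection and branch-length
formulas, with the reduced distances formed using the variance-minimizing
weight $\lambda \in [0,1]$ and the variance matrix initialized to the
distances and updated alongside them. The agglomeration is implemented in
the package in double precision, so additive matrices are recovered to
machine accuracy ($\le 10^{-9}$ path-length error is asserted; observed
errors are at the $10^{-15}$ level) and, on additive input, the reduction
is independent of $\lambda$ and the result coincides with plain neighbor
joining — the suite checks topological identity against an independent NJ
routine. Negative branch lengths (possible on non-additive input) are
clamped to zero and the clamped total recorded on the tree.
`extract_clusters()` cuts the tree into monophyletic clades of bounded
leaf-to-leaf path diameter; `max_depth = 0` yields singletons, `Inf` one
cluster.

## Abundance-weighted functional profiles

`sample_ko_profile()` computes, per sample, each KO's abundance as
$\sum_g \mathrm{copies}(g, \mathrm{KO}) \times \mathrm{abundance}(g)$: with
genomes A, B, C at abundances 1, 5 and 10 each encoding one copy, the KO's
abundance is 16. "Proportionally" is realized as copy-number weighting — a
genome encoding a KO twice contributes twice its abundance — and the
profile is exactly linear in the abundance matrix. Per-sample
renormalization to relative KO abundances is optional.
`annotate_best_hits()` builds the copy table from protein hit lists (best
hit per protein, e < $10^{-5}$).

## Virus/host ratios and differential abundance

The virus/host ratio of a taxon in a sample is the summed relative
abundance of viruses assigned to it divided by the taxon's abundance in the
paired cellular metagenome. Records with zero host abundance are flagged
undefined and **excluded** from correlations (not zero-imputed; their count
is reported). `vhr_association()` reports Spearman correlations between
host abundance and VHR per taxon (≥ 5 defined records) and pooled, with an
approximate Fisher-z 95% interval. A consistently negative association is
the abundance-domain signature of reduced lysis at high host density
(Piggyback-the-Winner); the simulator `simulate_vhr_records()` generates
$\mathrm{VHR} = \mathrm{host}^{-\gamma}\times\mathrm{noise}$ so the
direction recovery is testable with known $\gamma$.

`differential_abundance()` compares each feature between two sample groups
with the two-sided Mann–Whitney test and corrects across features with
Benjamini–Hochberg. When both groups have ≤ 8 samples the p-value is
computed by exhaustive enumeration of all group assignments over the pooled
average ranks — exact even under ties — mirroring the two-sided convention
of `wilcox.test` (double the smaller tail, capped at 1); larger groups use
the normal approximation with tie correction. The enriched group is the one
with the higher median (ties: higher mean; residual ties flagged `NA`
rather than guessed). BH is the standard realization of false discovery
rate control here; `p.adjust` supplies it and the suite verifies it against
a brute-force step-up.

## The synthetic community generator

`simulate_community()` provides ground truth for everything above: host
taxa with i.i.d. log-normal abundance across samples (log-sd 2 — the heavy
tails and large dynamic range typical of marine communities, and the
compositional structure the correlation model assumes), viruses whose
latent abundance is $c \cdot \mathrm{host} + (1-c) \cdot \mathrm{noise}$
with coupling $c$ and log-normal noise, and virome counts drawn
multinomially at fixed depth (sequencing reads are a fixed-size sample of a
composition, which a Poisson model would not enforce). Defaults — 20 hosts
× 3 viruses, 120 samples, coupling 0.95, depth $10^5$ — are the conditions
under which the end-to-end recovery property is stated: network host
prediction at genus rank, cutoff 0.6, reaches ≥ 0.9 accuracy averaged over
20 seeds, and accuracy at cutoff 0.6 is never below accuracy at cutoff 0.

What the generator deliberately does **not** emulate: sequence content
(no reads, no assembly artifacts, no chimeras), genome-length variation,
uneven per-sample depth, temporal autocorrelation between samples,
virus generalists (every virus has exactly one host), or host communities
structured by environment. Passing tests therefore demonstrate the
statistical machinery is correct under its own assumptions — not that real
viromes satisfy those assumptions.

## Numerical choices and problem sizes

* Correlations clamped to $[-1,1]$; basis variances to $\ge 10^{-8}$;
  Dice distances to $[0,1]$; branch lengths to $\ge 0$ — each clamp is
  logged or recorded.
* Ties broken deterministically everywhere (bitscore → e-value →
  lexicographic id; first-index pair selection in the NJ Q matrix).
* Degenerate inputs fail loudly: < 3 samples for variances, < 4 genomes for
  the basis system, < 3 taxa for trees, missing coverage or spacer-length
  columns, non-symmetric or NaN distance matrices.
* Seeds: every stochastic routine takes an explicit integer seed;
  inference iteration $k$ uses `seed + k − 1`.
* The suite runs at deliberately modest sizes — communities of 60–120
  genomes over 80–200 samples at depths $2\times 10^4$–$10^5$, 20 seeds for
  averaged properties, 100–1000 cases for brute-force cross-checks — chosen
  so the full suite completes in well under a minute per file while keeping
  every Monte-Carlo margin wide.

## Limitations

* The sparsity approximation behind the basis variances degrades when many
  genome pairs are strongly coupled; the exclusion heuristic mitigates but
  does not eliminate this (inherited from the estimator itself).
* Network host prediction requires the query to co-occur with some labelled
  reference; a virus infecting a host with no characterized viruses is
  unpredictable by construction, and accuracy claims transfer to real data
  only insofar as virus–host abundance coupling holds there.
* The Dice distance saturates at 1 for genome pairs sharing no qualifying
  homologue, so deep branches between unrelated clusters are not
  meaningfully proportional to divergence.
* VHR records with zero host abundance are informative about detection
  limits but are excluded from the correlation, which can bias the pooled
  estimate if zeros concentrate at one end of the host-abundance range.
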