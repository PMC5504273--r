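Package: viromenet
Title: Co-Occurrence Networks, Host Prediction and Comparative Genomics for
    Viral Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for analysing assembled viral genomes across collections
    of viromes. Builds genome-by-sample abundance matrices from read
    alignments with weighted reassignment of ambiguous reads, infers
    compositionally robust co-occurrence networks with a SparCC-style
    procedure, predicts phage hosts from the network (strongest positive
    correlation to a reference virus with a known host) as well as from
    alignment evidence (genome homology, bitscore-voting contig taxonomy,
    CRISPR spacers and tRNA matches), clusters genomes by Dice bitscore
    distances with BIONJ trees, computes abundance-weighted functional (KO)
    profiles, virus-to-host ratio statistics and group-wise differential
    abundance with false discovery rate control. A synthetic community
    simulator with known virus-host coupling provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    stats,
    utils
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
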