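Package: socgain
Title: Co-Gain Detection and Supra-Operonic Cluster Analysis of Horizontal
    Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects consistently co-gained gene-family pairs on a rooted
    bacterial phylogeny and relates their genomic distance distribution to
    supra-operonic clusters (SOCs) of co-occurring and co-functioning genes.
    Implements a two-state maximum-likelihood gain/loss model with marginal
    ancestral reconstruction, Fisher exact co-gain scores with a
    permutation-based empirical false discovery rate, circular-genome
    distance analysis with intervening phage-gene statistics, mutual
    information of phylogenetic profiles, delineation of gene-cluster
    distance distributions through genomic autocovariance, and a
    ground-truthed forward simulator of segmental and phage-mediated gene
    co-transfer for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
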