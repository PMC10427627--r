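Package: ampliclone
Title: Joint SNV and Copy-Number Clone Tree Inference from Single-Cell
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a rooted tree of somatic events (single-nucleotide
    variants and allele-specific copy-number alterations: gains, losses and
    copy-neutral loss of heterozygosity) from targeted single-cell amplicon
    sequencing read counts.  Read depths per region are modelled with a
    negative binomial distribution with per-region amplification weights,
    allelic counts with a beta-binomial mixture over allele-specific dropout
    configurations, and doublets as mixtures of node pairs.  Cell
    attachments are marginalised analytically; node weights and per-variant
    dropout rates are fitted by an expectation-maximisation algorithm nested
    inside a two-phase simulated-annealing search over event trees.
    Includes a generator of synthetic Tapestri-style panel data with ground
    truth and evaluation metrics for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
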