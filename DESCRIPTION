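Package: bcsvdmeth
Title: Case-Control DNA Methylation Analysis with Bayesian Classification and
    Singular Value Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for genome-wide CpG methylation array
    comparisons between small case and control groups, built around a
    simultaneous Bayesian classification test with singular value decomposition
    (BCSVD) dimension reduction, Gibbs-sampled probit model fitting, and
    permutation empirical p-values. Includes beta-value quality control
    (detection filtering, PCA outlier and covariate screening), cross-species
    probe validity filtering by ungapped alignment against a target genome with
    3'-anchor, mismatch and uniqueness criteria, leave-one-out
    cross-validation, generalized-likelihood-ratio power, hierarchical
    clustering, phenotype classification and association testing with multiple
    testing correction, and gene-set over-representation against a custom
    reference list. A synthetic-data module generates beta matrices, probe
    intensities, toy genomes with planted probe classes, and phenotype tables
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    nnet,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
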