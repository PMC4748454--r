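Package: plasmiR
Title: Baseline Profiling of the Circulating Plasma miRNAome from Small RNA Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of plasma circulating microRNA (miRNA) small RNA
    sequencing data: median-Phred read quality screening, 3' adapter trimming and
    15-35 nt length filtering, unique-sequence tallying, mismatch-tolerant (at most
    one substitution) assignment of reads to a mature miRNA reference, relative
    expression normalisation (percent of mapped miRNA reads), detection filtering,
    and baseline descriptors of a disease-free cohort: penetrance, top-k miRNA load
    fractions, normal expression ranges, expression stability ranking, and a
    blood-cell miRNA coefficient-of-variation haemolysis check. Includes
    covariate-group comparisons (sex, smoking, obesity) by two-tailed t-tests with
    linear-model elimination of nuisance factors and BMI correlation, plus a
    synthetic plasma cohort generator with ground truth for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
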