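Package: epistax
Title: Exhaustive Two-Locus Interaction Analysis for Case-Control SNP Studies
Version: 0.1.0
Authors@R:
    person("Epistax", "Maintainers", email = "maintainers@epistax.example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide scans of pairwise SNP interactions in
    case-control cohorts: a discrimination-gain (sensitivity/specificity)
    pair statistic with permutation-based p-value calibration, interaction
    odds ratios, classification of empirical two-locus penetrance models
    into canonical full-penetrance classes, likelihood-ratio tests of
    independence from known risk-haplotype dosages, multi-allelic linkage
    disequilibrium pruning of interaction signals (Hill's Q), and sparse
    L1-penalized squared-hinge predictive models with liability-scale
    variance accounting. Includes PLINK bed/bim/fam input/output, standard
    cohort quality control, and a seedable synthetic-cohort generator with
    LD-block haplotype structure and planted two-locus disease models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
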