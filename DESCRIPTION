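Package: clonepulse
Title: Clonal Dynamics of Chemotherapy-Treated Tumors from Copy-Number,
    Single-Cell, Expression and Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying intratumor clonal dynamics under
    chemotherapy in patient-derived xenograft models. Estimates mutated
    sample fractions, tumor cell fraction (purity) and mutated clone
    fractions from curated allele-specific copy-number segments and
    classifies aberrations as clonal or subclonal; calls copy-number
    aberration events from single-cell integer copy-number profiles on
    1-Mb bins with run-length curation cutoffs and groups cells into
    clones; reconstructs maximum-parsimony clone phylogenies from binary
    event matrices with homoplasy detection; computes intratumor
    heterogeneity statistics (stem-excluded copy-number aberration
    burden, Simpson's index of diversity, private-aberration fraction)
    and nesting-validated fish-plot data; scores gene signatures by
    average z score, selects top-variance genes, merges signatures and
    filters them by median-cut overall-survival association with false
    discovery rate control; classifies preclinical treatment response
    from caliper tumor-volume series. A full synthetic-data generator
    with planted ground truth accompanies every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    phangorn,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
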