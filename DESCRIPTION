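Package: etamr
Title: m6A Detection and Quantification from Global A-to-I Deamination Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling and quantifying N6-methyladenosine (m6A) from
    enzymatic A-to-I deamination sequencing (eTAM-seq style) count data.
    Implements the binomial maximum-likelihood estimator of per-site
    methylation stoichiometry, sample conversion-rate estimation, deaminase
    accessibility estimation from modification-free (IVT) controls with
    cross-validated linear shrinkage, a joint maximum-likelihood model for
    demethylase (FTO) controls, site calling via one-sided Fisher exact tests
    with Benjamini-Hochberg false-discovery control and exposed-methylation
    filtering, spike-in probe calibration, and downstream statistics
    (DRACH motif classification, site-clustering permutation tests,
    per-transcript methylation load and half-life comparisons). A built-in
    simulator generates transcriptomes, reads, count tables and probe sets
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
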