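Package: adcvigil
Title: Component-Stratified Disproportionality Analysis for Antibody-Drug
    Conjugate Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    adverse-event report databases, stratified by the structural components of
    antibody-drug conjugates (antibody subtype, linker cleavability, payload
    class, and drug-to-antibody ratio). Reads FAERS-style quarterly ASCII
    files or a simplified tabular dialect, deduplicates case versions,
    annotates suspect drugs with component classes, builds 2x2 contingency
    tables for every stratum-event pair, and computes four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio,
    information component, and the empirical Bayes geometric mean under a
    two-component gamma-Poisson mixture prior fitted by marginal likelihood).
    Signals require consensus across all four methods, are prioritized by
    reporting odds ratio rank, and are stress-tested with a Fisher exact /
    Benjamini-Hochberg false-discovery-rate sensitivity layer. A synthetic
    report generator with planted relative-reporting-rate effects supports
    end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
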