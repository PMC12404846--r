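Package: pvmr
Title: Pharmacovigilance Signal Detection and Drug-Target Mendelian
    Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for spontaneous-report pharmacovigilance and causal
    follow-up of flagged signals. Reads FAERS-style quarterly extracts
    (DEMO/DRUG/REAC), applies primary-suspect, reporter-occupation and
    case-deduplication filters, maps reaction preferred terms to renal
    standardized MedDRA query (SMQ) sets, and computes four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with chi-squared, the Bayesian confidence propagation
    neural network information component, and the empirical Bayes
    geometric mean) with their published decision thresholds. Signals
    that pass all four thresholds can be tested for causality with
    two-sample drug-target Mendelian randomization: cis-pQTL instrument
    selection, LD clumping, instrument-strength filtering, a
    positive-control validation gate, and Wald-ratio / inverse-variance
    weighted / MR-Egger / weighted-median / mode-based estimation with
    heterogeneity and pleiotropy diagnostics. A synthetic-data module
    generates FAERS-like report streams and GWAS/pQTL summary statistics
    with known ground truth so the full pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
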