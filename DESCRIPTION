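Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII tables: parsing and
    case-level deduplication, primary-suspect drug selection, MedDRA
    PT/SOC contingency tabulation, and four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio with
    chi-square, the BCPNN information component, and the DuMouchel
    gamma-Poisson shrinker EBGM) with their conventional signal
    criteria. Includes a descriptive report-characteristics summary, a
    synthetic FAERS-format report generator with analytic ground truth
    for calibration studies, and a utility that reconstructs 2x2 tables
    from published summary statistics for cross-validation of printed
    signal tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
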