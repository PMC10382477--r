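Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FDA Adverse Event Reporting System
    (FAERS) quarterly ASCII files: parsing of the DEMO/DRUG/REAC/THER/OUTC table
    dialect, CASEID-based report deduplication, primary-suspect drug screening
    against a synonym dictionary with multi-suspect exclusion, adverse-event
    extraction by MedDRA preferred term, 2x2 contingency tables and four
    disproportionality statistics (ROR, PRR with Pearson chi-squared,
    information component, empirical reporting ratio EBGM) with their signal
    criteria, co-medication sensitivity analysis, time-to-onset and serious
    outcome descriptive summaries, and a deterministic synthetic-corpus
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
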