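Package: faersage
Title: Age-Stratified Pharmacovigilance Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disproportionality analysis of FAERS-style spontaneous
    adverse-event reports, focused on age-stratified safety signals for CDK4/6
    inhibitors in breast cancer. Provides a synthetic FAERS-like report generator
    with planted reporting-odds effects, readers for the quarterly dollar-delimited
    ASCII tables, FDA-guidance deduplication, cohort construction with age strata
    and co-medication covariates, Standardised MedDRA Query (SMQ) mapping with
    hierarchy expansion, reporting odds ratio (ROR) screening with Wald intervals
    and the Haldane-Anscombe zero-cell correction, and a univariate-to-multivariate
    logistic regression cascade yielding adjusted odds ratios per age group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
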