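Package: telomr
Title: Mendelian Randomization of Telomere Length and Lung Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumental-variable analysis of leukocyte telomere length (TL)
    and lung cancer risk using TL-associated SNPs as instruments. Implements
    instrument selection and harmonization (kb-per-long-allele weights),
    weighted genetic-risk-score Mendelian randomization on individual-level
    case-control data, the inverse-variance-weighted (IVW) estimator on
    per-SNP summary statistics with Cochran-Q pleiotropy diagnostics and
    SNP-exclusion sensitivity refits, between-study heterogeneity tests,
    GRS decile trend analysis, and restricted-cubic-spline tests of
    nonlinearity in the dose-response. Ships a synthetic case-control cohort
    generator with the causal structure the method assumes (SNPs -> TL ->
    disease, confounders, optional direct pleiotropic paths) for calibration
    and power studies, plus a pipeline that runs both MR arms end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
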