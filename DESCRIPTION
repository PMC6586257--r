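Package: ironmr
Title: Mendelian Randomization Phenome-Wide Scans for Systemic Iron Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenome-wide two-sample Mendelian randomization (MR-PheWAS)
    of systemic iron status. Builds phecode case/control sets from ICD-9/10
    hospital-event tables with exclusion-range and relatedness pruning rules,
    fits covariate-adjusted per-SNP logistic regressions across the phenome,
    and combines the resulting summary statistics with genetic instrument
    associations for serum iron, ferritin, transferrin, and transferrin
    saturation via ratio estimates with second-order-weight standard errors,
    fixed-effect inverse-variance-weighted meta-analysis, Cochran Q
    heterogeneity screening, and a bootstrap weighted-median sensitivity
    estimator. Includes a seeded synthetic cohort generator emulating a
    biobank-scale study (Hardy-Weinberg genotypes, concordant iron biomarkers,
    logistic disease models, related pairs) so the full pipeline is testable
    without access to individual-level data.
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
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
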