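Package: myxofit
Title: Nutrient-History Effects on Cheating and Exploitation in Myxococcus Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for developmental competition assays in
    Myxococcus xanthus and similar aggregative microbes. Converts
    dilution-series colony counts from selective and non-selective plating
    into per-spot viable-spore estimates (pooled Poisson maximum likelihood,
    with 0.9-spore imputation at the limit of detection and marker-based
    deconvolution of mixed cultures), computes log-ratio social-fitness
    statistics (sporulation efficiency, relative fitness W and mixing effect
    C), runs the factorial nutrient-history inference (ANOVA, Bonferroni-Holm
    one-sample t tests, Tukey HSD and Dunnett contrasts), and emits
    qualitative cheating/exploitation outcome calls. Includes a synthetic
    experiment generator with closed-form ground truth for end-to-end
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    multcomp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
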