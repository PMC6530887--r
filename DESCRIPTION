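Package: uhcmonitor
Title: Monitoring Universal Health Coverage from Household Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring progress towards universal health coverage
    (UHC) from household-survey microdata. Generates seeded synthetic
    DHS-like coverage surveys and GLSS-like consumption surveys, constructs
    asset-based wealth indices by principal components and population-weighted
    quintiles, estimates survey-weighted coverage proportions with
    design-based (cluster-linearized) uncertainty, pools indicators into
    composite prevention/treatment indices by random-effects meta-analysis and
    the Boerma composite coverage index, measures financial hardship
    (catastrophic health expenditure, impoverishment and their union) from
    out-of-pocket health spending, quantifies wealth-related inequality by the
    slope and relative indices of inequality, and fits Bayesian logit-linear
    time trends (Gibbs sampler with an exact conjugate oracle) to project
    coverage to 2030 with probabilities of meeting UHC targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
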