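Package: vertmig
Title: Elevational Migration Phenology and Integrated Step-Selection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying elevational (altitudinal) migration of alpine
    ungulates from GPS collar data and gridded environmental fields. Provides
    double-logistic land-surface phenology fitting for NDVI and fractional
    snow cover series (green-up and snowmelt timing), terrain covariates
    (4-neighbour slope and aspect, escape terrain, exact Euclidean distance
    transforms), elevational net-displacement migration classification with
    timing and rate statistics, movement-kernel estimation (gamma step
    lengths, von Mises turning angles), integrated step-selection analysis
    via an in-package conditional logistic Newton solver with
    cluster-robust variance and QIC model comparison, random-intercept
    mixed-model trend summaries, and a seeded synthetic-landscape and
    track simulator with known ground truth for end-to-end validation.
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
    lme4,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    fitdistrplus,
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
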