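Package: sizeage
Title: Size-Age Population Assessment for Inland Trout Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end size-age stock assessment workflow for
    data-limited river salmonid populations. Fits length-weight allometry
    on log10 scales and imputes missing masses; fits and compares von
    Bertalanffy, Gompertz and logistic length-at-age trajectories by
    small-sample corrected AIC; estimates total mortality from the
    descending limb of a catch curve with an unbiased Chapman-Robson
    estimator and partitions it into natural and fishing components;
    derives empirical length-based reference points (length at first
    maturity, optimum harvest length, harvest slot); evaluates
    minimum-length and harvest-slot regulations against a length-frequency
    catch sample; and computes numerical and biomass densities from
    electrofishing transects. Includes an age-structured synthetic
    population generator for validating every stage without field data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
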