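Package: clutchvis
Title: Avian Visual Modelling of Egg Colour Variation and Egg-Rejection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensory-ecology analyses of eggshell coloration.
    Processes reflectance spectra (replicate averaging, regridding,
    triangular smoothing, sensitivity padding), computes tetrachromatic
    receptor-noise-limited quantum catches and chromatic/achromatic
    just-noticeable differences (JNDs), compares within- versus
    between-clutch discriminability with heteroscedastic one-way tests on
    disjoint random egg pairings, and analyses three-arm egg-rejection
    experiments with exact and Monte-Carlo Fisher tests, Cramer's V,
    noncentral chi-square power and sample-size calculations, and a
    binomial logistic regression with covariates. Includes seeded
    generators for clutch-structured synthetic spectra, template
    photoreceptor sensitivities, illuminants, and rejection outcomes so
    the full pipeline is testable without field data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
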