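Package: litterindex
Title: Detection Power and Geostatistical Density Indices for Seafloor Litter Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well transect-based underwater video
    surveys detect seafloor litter, and for building standardized annual
    litter-density indices from bottom-trawl survey data. Includes a
    grid-based transect-sampling simulator with closed-form zero-detection
    companions (rule of three, Agresti-Coull intervals), a Poisson-link
    delta-Gamma geostatistical mixed model with anisotropic Matern spatial
    and AR1 spatiotemporal random fields estimated by maximum marginal
    likelihood via the Laplace approximation, annual index extraction with
    a CV-weighted trend, and a synthetic survey-data generator for testing
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    TMB
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
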