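Package: fracmsm
Title: Multistate Modelling of Fracture, Refracture, and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state continuous-time Markov multistate model of bone
    health for people aged 60 and over: fracture-free, first, second and
    third-plus fracture, and death as an absorbing state. Builds
    covariate-dependent transition-intensity (generator) matrices, computes
    matrix-exponential transition probabilities, expected sojourn times and
    cumulative mortality, fits transition intensities to exactly observed or
    panel-observed event histories by maximum likelihood, and translates
    mortality hazard ratios into an effective "skeletal age". Includes a
    synthetic-cohort generator emulating the structure of the Dubbo
    Osteoporosis Epidemiology Study so that every pipeline stage is testable
    without access to the original cohort.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
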