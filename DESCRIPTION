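Package: censgrowth
Title: Bayesian Tumour Growth Modelling with Censored Volume Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits ordinary-differential-equation tumour-growth models
    (exponential, capped exponential, Gompertz, logistic and Richards
    generalised logistic) to longitudinal tumour-volume measurements with
    multiplicative log-normal error, handling volumes censored at lower and
    upper limits of detection through an error-function likelihood rather
    than discarding them. Provides linear- and log-uniform priors, an
    affine-invariant ensemble ("stretch move") Markov chain Monte Carlo
    sampler, profile log-likelihood curves for practical identifiability,
    local parameter sensitivity, narrowest-contiguous credible intervals,
    solution-curve envelopes, and a synthetic mouse-cohort generator that
    emulates calliper studies with euthanasia dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
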