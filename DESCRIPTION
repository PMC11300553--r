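Package: smchr
Title: Built-In Selection Bias of Hazard Ratios Under Latent Frailty and
    Effect Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the causal hazard ratio (CHR) and the survivor
    marginalized causal hazard ratio (SMCHR) for multiplicative-hazard
    structural causal models with latent frailty and latent effect
    modification. Provides Laplace-transform machinery for gamma, inverse
    Gaussian, compound Poisson and three-point benefit-harm-neutral latent
    laws, analytic and Monte Carlo SMCHR curves, Gaussian-copula coupling of
    frailty and modifier, a potential-outcome simulator for randomized
    trials with administrative and exponential loss-to-follow-up censoring,
    and evaluation of the estimand targeted by a misspecified proportional
    hazards fit.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    readr,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
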