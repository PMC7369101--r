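Package: admarkov
Title: Markov Cohort Modelling and Cost-Effectiveness Analysis Across the
    Alzheimer's Disease Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for health-economic modelling of the Alzheimer's disease
    continuum, from mild cognitive impairment (AD-MCI) through mild, moderate
    and severe dementia. Provides a synthetic longitudinal dementia-registry
    generator with known ground truth, registry cleaning and MMSE-based
    severity staging, annualised state-transition extraction, estimation of
    ordered-probit transition models with inverse-probability-of-censoring
    weighting, Weibull mortality on the age time-scale, gamma cost regressions
    and age-linear utilities, a five-state Markov cohort engine with
    half-cycle correction and discounting, incremental cost-effectiveness
    analysis of hypothetical disease-modifying treatments (ICER, net monetary
    benefit, numbers needed to treat, threshold prices), and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    MASS,
    survival,
    flexsurv,
    stats,
    jsonlite,
    yaml,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
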