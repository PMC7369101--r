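---
title: "Modelling the Alzheimer's disease continuum: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Alzheimer's disease continuum: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admarkov)
library(dplyr)
```

## The problem

People with mild cognitive impairment due to Alzheimer's disease (AD-MCI)
face a high lifetime risk of progressing to AD-dementia, and the societal
costs of the dementia years dwarf those of the predementia period. A
disease-modifying treatment (DMT) that merely slows progression would
change when — not whether — most patients reach dementia, so its value can
only be judged over a lifetime horizon. `admarkov` implements a five-state
Markov cohort model (AD-MCI, Mild, Moderate and Severe AD-dementia, Death)
for exactly this question, together with the estimation stack that turns
longitudinal dementia-registry data into the model's inputs and the
cost-effectiveness layer that evaluates hypothetical DMTs.

The package has four parts:

1. a **synthetic registry generator** with known ground truth, standing in
   for national dementia-registry data that cannot be redistributed;
2. **registry preparation**: cleaning rules, MMSE severity staging, annual
   grid interpolation and transition extraction;
3. **estimation**: inverse-probability-of-censoring weights, an ordered
   probit for one-year cognitive transitions, Weibull mortality on the age
   time-scale, a gamma cost regression, and an age-linear utility model;
4. the **cohort engine and economics**: 40 annual cycles with half-cycle
   correction and 3% discounting, intervention effects, ICER / NMB / NNT /
   threshold prices, one-way scenarios and probabilistic sensitivity
   analysis.

## The cohort model

The cohort (default 100,000 persons, all in AD-MCI at age 60) is propagated
through one-year cycles for 40 years. Each cycle's transition matrix is
composed from three pieces:

* **Progression out of AD-MCI.** The base case converts a 3-year
  progression risk of 50% into a constant annual risk with
  $p_{1y} = 1 - (1 - p_{3y})^{1/3} = 20.6\%$ (`annualize_risk()`). A
  sensitivity variant lets the risk decline by a relative 10% per model
  year (`time_dependent_risk()`), giving 18.5% in year two. AD-MCI can move
  only to Mild dementia or death; direct jumps to Moderate/Severe are
  structurally excluded.

* **Transitions within dementia.** A row-stochastic matrix over the living
  states, either supplied directly (the calibrated reference set) or
  derived from a fitted ordered probit. Backward transitions (e.g.
  Moderate back to Mild) are allowed by default because registries show
  them; a `no_backward` switch folds that mass onto the diagonal.

* **Mortality.** The death column uses the age-specific general-population
  probability $q(a)$ and severity hazard ratios through
  $p_{death} = 1 - \exp(-q(a) \cdot HR)$ (`death_probability()`). This
  composition multiplies the *probability*, not a converted rate, inside
  the exponent; we reproduce it in exactly that form because it is the
  published estimator, and expose the mathematically cleaner
  $1 - (1-q)^{HR}$ behind `method = "rate"`. The living-state row is then
  rescaled to $1 - p_{death}$. A low-mortality variant predicts one-year
  death probabilities directly from a Weibull fit on the age time-scale
  (Very mild pooled with Mild) instead of multiplying the life table.

Person-years, costs and QALYs accrue with the trapezoid form of the
half-cycle correction: the average of beginning- and end-of-cycle occupancy.
Accruals of cycle $t$ are discounted by $(1+r)^{-t}$ (end-anchored; a
mid-cycle exponent $t - 0.5$ is available in `discount_factor()`). The Death
state accrues nothing; dying persons contribute the half cycle implied by
the occupancy average. Incident dementia counts the MCI-to-Mild flow only,
the single doorway into dementia. Age advances one year per cycle for the
whole cohort; residual survivors at the horizon are reported, never forced
into Death.

## What the synthetic registry emulates

`generate_registry()` simulates the data-generating features that the
estimation stack must cope with:

* a baseline (diagnosis) visit followed by annual follow-ups with Gaussian
  timing jitter (default sd one month);
* a severity path whose one-year transitions are *exactly*
  ordered-probit: the next latent value is a previous-state shift plus an
  age-75 shift plus standard normal noise, cut at fixed thresholds. Integer
  MMSE is drawn within the current state's band, so staging recovers the
  state without error while interpolation still sees realistic score
  jitter;
* mortality layered on a life table via the same probability-times-HR
  composition the engine uses;
* drop-out decided at the *last attended* visit, logistic in the severity
  seen there. This makes censoring missing-at-random given the observed
  history — exactly the selection IPCW corrects — and it is the package's
  own modelling choice: registries describe annual follow-up but not a
  drop-out law;
* optional labelled corruption (too-short intervals, duplicate dates,
  visits after death, persons without MMSE) so the cleaner's exclusion
  counts can be checked against construction.

What it does **not** emulate: diagnosis-type mixtures, biomarker or imaging
variables, measurement error that crosses severity bands, calendar-time
effects, or drop-out that depends on the unobserved next state. Passing the
recovery tests therefore shows the estimators are correct under a
well-behaved MAR mechanism at registry scale — not that any real registry
satisfies those assumptions.

## Registry preparation

Cleaning applies the registry's error filters in a fixed order, so each
removed row has exactly one attributed cause: unparseable dates; persons
without a dated baseline; follow-ups before baseline; follow-ups after
death; duplicate dates (first kept); observations less than four months
after the previous *kept* observation; and finally persons left with no
MMSE at all. Duplicates are attributed before the short-interval rule: a
duplicate has interval zero and would otherwise be swallowed by it, and the
kept set is identical under either order. The four-month comparison is
against the previous kept (not raw) observation — the rule has to be
applied to something, and the kept sequence is the deterministic choice.

MMSE is then linearly interpolated onto anniversaries of each person's
baseline visit; beyond the last visit, linear extrapolation from the last
two visits is allowed for at most three months, and never backwards before
the first measurement. Interpolated values stay fractional until staging,
where they are rounded half-up because the severity cut-offs are integers
(Mild 21–30, Moderate 10–20, Severe 0–9; Very mild 27–30 in the 4-level
scheme used for mortality). Consecutive grid years become transitions; a
death within one year of the last grid point becomes a transition to Death;
anything else ends in censoring one year after the last available MMSE.

## Estimation

* **Censoring and IPCW.** A logistic model of remaining under observation
  given current state and age feeds weights equal to the inverse cumulative
  continuation probability. Stabilization by the marginal continuation rate
  and truncation at the 99th percentile are on by default; both are
  standard variance-control devices and switchable.
* **Ordered probit.** `MASS::polr(method = "probit")` on the one-year-ahead
  cognitive state with previous-state indicators and an age≥75 indicator
  (age otherwise does not enter; the data behind the design showed
  transition probabilities independent of age except at that split).
  Death is deliberately *not* an outcome level: mortality is estimated
  separately and overlaid by the engine, keeping the two risks orthogonal
  in the inputs.
* **Weibull mortality.** `flexsurv::flexsurvreg(dist = "weibullPH")` on
  counting-process records with age as the time scale (left truncation at
  each interval's entry age). Starting values are derived from the crude
  event rate because the default initializer struggles with left-truncated
  age-scale data. Hazard ratios are read off the proportional-hazards
  coefficients; Very mild (MMSE 27–30) is the reference level, and a
  variant pools Very mild with Mild for the low-mortality scenario.
* **Costs.** A log-link gamma GLM of annual societal cost on age and
  severity state (`stats::glm`).
* **Utilities.** The age-linear EQ-5D-3L relation
  $u(a) = -0.002464\,a + 0.962679$ with per-state decrements and the same
  age slope in every state. The formula is applied to raw age by default;
  the alternative reading that anchors it at age 25 is exposed as
  `age_offset = 25` without asserting which was intended. Utilities are
  clamped to the EQ-5D-3L value-set range $[-0.594, 1]$ and Death has
  utility 0.

## The reference input set is a calibration, not data

The exact per-state transition rows, costs and state utilities behind the
published cohort results live in supplementary material that is not
available. `reference_inputs()` therefore ships values chosen **once** so
that the base-case run lands near the headline behaviour — mean survival
about 19 years, roughly 96% cumulative dementia, about half the cohort dead
by year 20 — and they are documented as calibration choices. Notably the
Severe-state hazard ratio (7.0) is a calibration knob that also absorbs the
probability-based mortality composition at late ages; it should not be read
as a survival-analysis estimate. With these inputs the 40-year run prints a
per-person NPV cost near 4.47 million SEK, 7.84 QALYs, and a discounted
cost per dementia person-year near 253,000 SEK.

## Intervention and economics

The base intervention multiplies forward progression out of AD-MCI and out
of Mild dementia by $1 - RRR$ (default 25%), moving the freed mass onto the
stay probability. Backward transitions and death probabilities are
untouched: the treatment slows deterioration, it does not resurrect
cognition or directly alter mortality — survival gains arise only through
state redistribution. Treatment cost (default 50,000 SEK/year) accrues per
half-cycle-corrected, discounted person-year actually spent in a treated
state inside the treatment window, not per initiated person.

Because price enters the incremental cost linearly through those discounted
treated person-years, the budget-neutral price and the price at which
NMB(λ) = 0 are solved in closed form; a bisection over re-run comparisons
confirms the roots in the test-suite. NNT is cohort size over avoided
cumulative dementia cases, rounded half-up. The ICER is flagged undefined
when the QALY increment is below tolerance rather than returning an
unstable ratio.

## Probabilistic sensitivity analysis

Each PSA iteration draws, independently: the treatment price and state
costs from gamma distributions parameterized by (mean, SE); the MCI
progression risk and state utilities from moment-matched beta
distributions (SE truncated if infeasible; logit-normal available); and
positive scalings of within-dementia progression and mortality from gamma.
The standard error is 25% of the mean by default and both arms share each
iteration's draws. Age-varying inputs are frozen at their age-71 values for
PSA runs only, so iterations differ in parameters rather than in the age
profile; 1,000 iterations is the intended production size, and the
acceptability curve reports, per willingness-to-pay value on a 0–1.2M SEK
grid, the fraction of iterations with positive net monetary benefit (exact
ties count as not cost-effective). Parameters are drawn independently —
no correlation structure is asserted because none is known.

## Numerical choices and degenerate inputs

* Transition-matrix rows are validated to sum to 1 within $10^{-12}$ at
  composition time; any negative entry is an internal error, not a warning.
* Half-up rounding (`floor(x + 0.5)`) is used wherever a published integer
  is reproduced (staging of fractional MMSE, NNT) because banker's rounding
  would disagree with printed values on exact halves.
* A single visit yields only the baseline grid point; no extrapolation is
  attempted from one observation.
* Strata with no deaths make the Weibull fit fail with the stratum named;
  complete separation in the censoring model is reported with the runaway
  coefficients.
* `compute_nnt()` returns `NA` (undefined) when no cases are avoided, and
  the ICER carries an explicit `icer_defined` flag.

## Problem sizes used in the test-suite

Simulation-based tests run at sizes chosen to keep Monte-Carlo error small
relative to their tolerances while the whole suite stays quick: parameter
recovery uses cohorts of 5,000 persons over seeds 1–5 (about 20,000 annual
transitions per seed), convergence checks use 4,000–5,000 persons, and PSA
property checks use 25–40 iterations. Recovery tolerances are three
standard errors of the corresponding estimate, never a fixed band tuned to
a particular draw.

## Known limitations

* The model is a cohort model: everyone shares one start age and one clock.
  Questions about stopping rules or state-dependent treatment duration
  need individual-level microsimulation, which is out of scope.
* No calendar-time demography, cohort replenishment or prevalence
  projection.
* The probability-times-HR mortality composition overstates death at high
  ages relative to a rate-based composition; both are available, the
  published form is the default.
* The reference inputs are calibrated, so absolute cost levels produced
  with them illustrate magnitudes; only the structural and arithmetic
  properties are asserted by tests.
* PSA draws are independent across parameters; correlated uncertainty
  (e.g. between state costs) is not modelled.
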