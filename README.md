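# admarkov

Health-economic modelling of the Alzheimer's disease (AD) continuum:
a five-state Markov cohort model from mild cognitive impairment due to AD
(AD-MCI) through Mild, Moderate and Severe AD-dementia to death, with the
estimation stack that turns longitudinal dementia-registry data into model
inputs and a cost-effectiveness layer for hypothetical disease-modifying
treatments (DMTs).

It is written for health economists and biostatisticians who want a tested,
scriptable counterpart to the spreadsheet/TreeAge-style cohort models used
in dementia health-technology assessment.

## The model

A cohort of 100,000 persons with AD-MCI (start age 60) is propagated
through 40 one-year cycles with half-cycle correction and 3% discounting.
Each cycle's 5×5 transition matrix combines:

* progression out of AD-MCI at the annualized rate
  *p*₁ = 1 − (1 − *p*₃)^(1/3) (3-year risk 50% → 20.6%/year), optionally
  declining by a relative 10% per model year;
* a row-stochastic matrix of one-year transitions between dementia states,
  either supplied directly or predicted from an ordered probit on the
  previous state and an age ≥ 75 indicator, fitted to annualized registry
  transitions with inverse-probability-of-censoring weights (IPCW);
* mortality composed from a general-population life table and severity
  hazard ratios (Weibull fit, age time-scale) via
  *p*(death) = 1 − exp(−*q*(age)·HR).

Costs come from a log-link gamma GLM (or a per-state table, SEK 2016);
utilities from the age-linear EQ-5D-3L relation
*u*(age) = −0.002464·age + 0.962679 with per-state decrements. A treatment
is a relative risk reduction (RRR) on forward progression in treated states
plus an annual price; the package reports ΔCost, ΔQALY, ICER = ΔC/ΔQ,
net monetary benefit λ·ΔQ − ΔC, numbers needed to treat, threshold prices
(budget-neutral and NMB = 0), one-way scenario batteries, and probabilistic
sensitivity analysis with acceptability curves.

Because the registry behind the original analysis is not public, the
package ships (a) a synthetic registry generator with known ground truth —
probit-structured severity transitions, life-table mortality with hazard
ratios, severity-dependent informative drop-out, gamma costs — so the whole
estimation pipeline is testable end-to-end, and (b) a calibrated reference
input set (`reference_inputs()`) whose base-case run approximates the
headline cohort behaviour (mean survival ≈ 19 years, ≈ 96% cumulative
dementia, ≈ half the cohort dead by year 20). The reference values are
calibration choices, not registry estimates; see the methods vignette.

## Worked example

```r
library(admarkov)

inp     <- reference_inputs()                 # calibrated base case
control <- run_cohort(inp)                    # natural history
treated <- run_cohort(inp, intervention_spec())  # 25% RRR, 50,000 SEK/yr
control
#> <cohort_trajectory> 40 cycles, cohort 1e+05, start age 60
#>   cumulative dementia 95787, deaths 99406, PY/person 19.02
#>   NPV cost/person 4471773 SEK, QALYs/person 7.84

cea <- compare_arms(control, treated, wtp = 600000)
cea
#> <cea_result>
#>   dCost 294842 SEK, dQALY 0.7176, ICER 410885, NMB(6e+05) 135705
#>   threshold price: budget-neutral 17027, NMB=0 65176 SEK/year
```

Reading the output: under the calibrated inputs, almost everyone (95,787 of
100,000) develops dementia and mean survival is 19.0 years. Treating in
AD-MCI and Mild dementia adds 294,842 SEK and 0.72 QALYs per person in net
present value, an ICER of about 411,000 SEK per QALY — below the 600,000
SEK willingness-to-pay, so the treatment is cost-effective there but far
from cost-saving: its price would have to fall to about 17,000 SEK/year to
break even on costs alone. The final-horizon NNT (`glance(cea)`) is 45
(2,246 avoided cases).

Every result type has `tidy()`/`glance()` methods and plots:

```r
autoplot(control)                      # state occupancy over 40 years
psa <- run_psa(psa_spec(inp, intervention_spec(), n_iter = 1000), seed = 1)
autoplot(psa)                          # cost-effectiveness acceptability curve
scenario_battery(inp, intervention_spec(),
                 scenarios = list(rrr50 = list(rrr = 0.5),
                                  r1    = list(discount_rate = 0.01)))
```

An end-to-end synthetic run — generate registry → clean → annualize →
estimate all four models → simulate → CEA → PSA, with checksummed artifacts
— is one call:

```r
run_pipeline(run_config(out_dir = "results", seed = 1),
             mode = "synthetic_end_to_end")
```

## Package layout

| file | contents |
|---|---|
| `R/synthetic_registry.R` | generator, life table, ground truth, cost records |
| `R/registry_prep.R` | cleaning rules, annual grid, transition extraction |
| `R/estimation.R` | censoring/IPCW, ordered probit, Weibull mortality, gamma costs, utilities |
| `R/markov.R` | annualization, discounting, matrix composition, cohort engine, summaries |
| `R/cea.R` | interventions, incremental measures, NNT, threshold prices, scenarios |
| `R/psa.R` | parameter draws, PSA runs, acceptability curves |
| `R/pipeline.R` | configuration and end-to-end orchestration |
| `vignettes/admarkov-methods.Rmd` | model assumptions, design choices, limitations |
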