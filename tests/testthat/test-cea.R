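test_that("treatment effect rescales forward progression into the diagonal", {
  row <- c(MCI = 0.794, Mild = 0.206, Moderate = 0, Severe = 0, Death = 0)
  out <- apply_intervention(row, "MCI", intervention_spec(rrr = 0.25))
  expect_equal(unname(out), c(0.8455, 0.1545, 0, 0, 0), tolerance = 1e-12)
  # identity at rrr = 0, total stop at rrr = 1
  expect_equal(apply_intervention(row, "MCI", intervention_spec(rrr = 0)), row)
  stop <- apply_intervention(row, "MCI", intervention_spec(rrr = 1))
  expect_equal(unname(stop), c(1, 0, 0, 0, 0))
  # death probability untouched, row still sums to one
  row2 <- c(MCI = 0, Mild = 0.6, Moderate = 0.25, Severe = 0.05, Death = 0.10)
  out2 <- apply_intervention(row2, "Mild", intervention_spec(rrr = 0.25))
  expect_equal(unname(out2[["Death"]]), 0.10)
  expect_equal(sum(out2), 1, tolerance = 1e-12)
  # backward transitions out of a dementia state are left unchanged
  row3 <- c(MCI = 0, Mild = 0.08, Moderate = 0.7, Severe = 0.12, Death = 0.10)
  out3 <- apply_intervention(row3, "Moderate", intervention_spec(rrr = 0.5))
  expect_equal(unname(out3[["Mild"]]), 0.08)
  expect_equal(unname(out3[["Severe"]]), 0.06)
})

test_that("incremental arithmetic reproduces the published example", {
  r <- cea_from_npv(4503751, 4893703, 7.90, 8.63, wtp = 600000)
  expect_equal(r$delta_cost, 389952)
  expect_equal(r$delta_qaly, 0.73, tolerance = 1e-12)
  expect_equal(r$nmb, 600000 * 0.73 - 389952, tolerance = 1e-9)
  expect_equal(r$nmb, 48048, tolerance = 1e-9)
  # ICER from rounded increments agrees with the printed ratio within 0.5%
  expect_lt(abs(r$icer - 532519) / 532519, 0.005)
})

test_that("NNT is the half-up rounded inverse of the avoided-case fraction", {
  expect_equal(compute_nnt(100000, 2447), 41)
  expect_equal(compute_nnt(100, 100), 1)
  expect_equal(compute_nnt(100, 50), 2)
  expect_true(is.na(compute_nnt(100, 0)))
  expect_true(is.na(compute_nnt(100, -5)))
})

test_that("identical arms give zero increments and an undefined ICER", {
  inp <- reference_inputs(horizon = 15)
  ctrl <- run_cohort(inp)
  null_trt <- run_cohort(inp, intervention_spec(rrr = 0, annual_cost = 0))
  res <- compare_arms(ctrl, null_trt, horizons = 15)
  expect_equal(res$delta_cost, 0, tolerance = 1e-9)
  expect_equal(res$delta_qaly, 0, tolerance = 1e-12)
  expect_false(res$icer_defined)
  expect_true(is.na(res$icer))
  expect_equal(res$nmb, 0, tolerance = 1e-9)
})

test_that("the base intervention shifts person-years toward early states", {
  inp <- reference_inputs()
  ctrl <- run_cohort(inp)
  trt <- run_cohort(inp, intervention_spec())
  res <- compare_arms(ctrl, trt)
  d <- setNames(res$delta_py$delta, res$delta_py$state)
  expect_gt(d[["MCI"]], 0)          # longer time in MCI under treatment
  expect_gt(res$delta_py_total, 0)  # small overall survival gain
  expect_lt(d[["Moderate"]] + d[["Severe"]], 0)
  expect_gt(res$delta_qaly, 0)
  expect_true(all(res$nnt$nnt >= 1, na.rm = TRUE))
  # avoided cases accumulate with horizon
  expect_true(all(diff(res$nnt$avoided_cases) < 0 | diff(res$nnt$avoided_cases) > 0))
  expect_gt(res$nnt$avoided_cases[res$nnt$horizon == 40], 0)
})

test_that("threshold prices solve the affine incremental-cost equation", {
  inp <- reference_inputs()
  ctrl <- run_cohort(inp)
  spec <- intervention_spec()
  trt <- run_cohort(inp, spec)
  res <- compare_arms(ctrl, trt)
  bn <- threshold_price(res, "budget_neutral")
  nz <- threshold_price(res, "nmb_zero")
  # independent root-finder over re-run comparisons
  dc_at <- function(price) {
    sp <- intervention_spec(annual_cost = price)
    compare_arms(ctrl, run_cohort(inp, sp))$delta_cost
  }
  bn_bisect <- uniroot(dc_at, c(0, 200000), tol = 1e-6)$root
  expect_equal(bn, bn_bisect, tolerance = 1e-6)
  nmb_at <- function(price) {
    sp <- intervention_spec(annual_cost = price)
    compare_arms(ctrl, run_cohort(inp, sp))$nmb
  }
  nz_bisect <- uniroot(nmb_at, c(0, 500000), tol = 1e-6)$root
  expect_equal(nz, nz_bisect, tolerance = 1e-6)
  # a positive QALY gain pushes the WTP threshold above budget neutrality
  expect_gt(nz, bn)
  # affinity: delta cost at the budget-neutral price is zero
  expect_equal(dc_at(bn), 0, tolerance = 1e-3)
})

test_that("stronger effects avoid more cases and improve the ICER", {
  inp <- reference_inputs()
  bat <- scenario_battery(inp, intervention_spec(),
                          scenarios = list(rrr50 = list(rrr = 0.5)))
  base <- bat[bat$scenario == "base", ]
  strong <- bat[bat$scenario == "rrr50", ]
  expect_gt(strong$avoided_cases, base$avoided_cases)
  expect_lt(strong$icer, base$icer)
  expect_lt(strong$nnt, base$nnt)
})

test_that("starting treatment in Mild dementia yields a higher ICER than in MCI", {
  inp <- reference_inputs()
  bat <- scenario_battery(inp, intervention_spec(),
                          scenarios = list(late = list(treated_states = "Mild")))
  expect_gt(bat$icer[bat$scenario == "late"], bat$icer[bat$scenario == "base"])
})

test_that("discount-rate scenarios preserve the published cost ordering", {
  inp <- reference_inputs()
  bat <- scenario_battery(inp, intervention_spec(),
                          scenarios = list(r1 = list(discount_rate = 0.01),
                                           r5 = list(discount_rate = 0.05)))
  cc <- setNames(bat$cost_control, bat$scenario)
  expect_gt(cc[["r1"]], cc[["base"]])
  expect_gt(cc[["base"]], cc[["r5"]])
  qq <- setNames(bat$qaly_control, bat$scenario)
  expect_gt(qq[["r1"]], qq[["base"]])
  expect_gt(qq[["base"]], qq[["r5"]])
})

test_that("the scenario battery validates knob names and supports all knobs", {
  inp <- reference_inputs()
  expect_error(scenario_battery(inp, intervention_spec(),
                                scenarios = list(bad = list(frobnicate = 1))),
               class = "admarkov_parameter_error")
  bat <- scenario_battery(
    inp, intervention_spec(),
    scenarios = list(
      total_stop = list(rrr = 1),
      age70 = list(start_age = 70, horizon = 30),
      decay = list(risk_decline = 0.10),
      nobk = list(no_backward = TRUE),
      lowmort = list(low_mortality = TRUE)),
    mortality_low = attr(inp, "mortality_low"))
  expect_equal(nrow(bat), 6)
  expect_true(all(bat$avoided_cases > 0))
  # the low-mortality variant keeps substantially more of the cohort alive
  expect_error(scenario_battery(inp, intervention_spec(),
                                scenarios = list(lowmort = list(low_mortality = TRUE))),
               class = "admarkov_parameter_error")
})

test_that("mismatched horizons are rejected in comparisons", {
  ctrl <- run_cohort(reference_inputs(horizon = 10))
  trt <- run_cohort(reference_inputs(horizon = 12), intervention_spec())
  expect_error(compare_arms(ctrl, trt), class = "admarkov_parameter_error")
})
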