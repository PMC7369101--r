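#' Specify a hypothetical disease-modifying treatment
#'
#' The base intervention reduces the progression risk out of AD-MCI by 25%
#' and the forward progression rate within Mild AD-dementia by 25%, costs
#' 50,000 SEK per treated person-year, starts at age 60, and may last the
#' whole horizon.
#'
#' @param rrr Relative risk reduction on forward progression, in `[0, 1]`.
#' @param treated_states States in which treatment (effect and cost) applies.
#' @param annual_cost Treatment cost, SEK per treated person-year.
#' @param start_age Age at which treatment starts.
#' @param duration Maximum treatment duration in years.
#' @param id Scenario label.
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(rrr = 0.25,
                              treated_states = c("MCI", "Mild"),
                              annual_cost = 50000,
                              start_age = 60, duration = 40,
                              id = "base_intervention") {
  check_prob(rrr, "rrr")
  if (annual_cost < 0) stop_param("`annual_cost` must be >= 0")
  if (!all(treated_states %in% living_states)) {
    stop_param("`treated_states` must be living states")
  }
  structure(list(rrr = rrr, treated_states = treated_states,
                 annual_cost = annual_cost, start_age = start_age,
                 duration = duration, id = id),
            class = "intervention_spec")
}

# states treated during the cycle at this age (empty if outside window)
treated_now <- function(spec, age, cycle) {
  if (age < spec$start_age) return(character(0))
  if (age - spec$start_age >= spec$duration) return(character(0))
  spec$treated_states
}

#' Apply a treatment effect to one transition-matrix row
#'
#' Multiplies the forward-progression probabilities out of the treated state
#' by `1 - rrr` and adds the freed mass to the stay probability. Backward
#' transitions and the death probability are unchanged; the row still sums
#' to 1.
#'
#' @param row Named numeric row of a full 5x5 matrix (states + Death).
#' @param state The state the row belongs to.
#' @param spec An [intervention_spec()].
#' @return The modified row.
#' @export
apply_intervention <- function(row, state, spec) {
  idx <- match(state, model_states)
  forward <- model_states[seq_along(model_states) > idx &
                            model_states != "Death"]
  freed <- sum(row[forward]) * spec$rrr
  row[forward] <- row[forward] * (1 - spec$rrr)
  row[state] <- row[state] + freed
  row
}

#' Incremental cost-effectiveness from per-person net present values
#'
#' Core incremental arithmetic shared by [compare_arms()]: incremental cost,
#' incremental QALYs, ICER (flagged undefined when the QALY gain is below
#' tolerance) and net monetary benefit at a willingness-to-pay level.
#'
#' @param cost_control,cost_treated Per-person NPV costs, SEK.
#' @param qaly_control,qaly_treated Per-person NPV QALYs.
#' @param wtp Willingness to pay per QALY, SEK (default 600,000).
#' @param tol Incremental-QALY tolerance below which the ICER is undefined.
#' @return A tibble with `delta_cost`, `delta_qaly`, `icer`,
#'   `icer_defined`, `nmb`.
#' @examples
#' cea_from_npv(4503751, 4893703, 7.90, 8.63)
#' @export
cea_from_npv <- function(cost_control, cost_treated,
                         qaly_control, qaly_treated,
                         wtp = 600000, tol = 1e-9) {
  dc <- cost_treated - cost_control
  dq <- qaly_treated - qaly_control
  defined <- abs(dq) > tol
  tibble(delta_cost = dc, delta_qaly = dq,
         icer = ifelse(defined, dc / dq, NA_real_),
         icer_defined = defined,
         nmb = wtp * dq - dc)
}

#' Number needed to treat to avoid one dementia case
#'
#' `N / avoided`, rounded half-up to an integer. Returns `NA` (undefined,
#' not an error) when no cases are avoided.
#'
#' @param n_cohort Cohort size.
#' @param avoided Avoided cumulative dementia cases at the horizon.
#' @return Integer NNT, or `NA` if `avoided <= 0`.
#' @examples
#' compute_nnt(100000, 2447)  # 41
#' @export
compute_nnt <- function(n_cohort, avoided) {
  ifelse(avoided > 0, round_half_up(n_cohort / avoided), NA_real_)
}

#' Compare a control and a treated cohort run
#'
#' Computes the incremental cost-effectiveness result from two trajectories
#' run on identical inputs except the intervention: per-person NPV costs
#' (state costs plus treatment cost) and QALYs, incremental person-years by
#' state, ICER, NMB, NNT by horizon, cost per dementia-free person-year,
#' cost per prolonged person-year, and threshold prices (budget-neutral and
#' NMB = 0 at the willingness to pay).
#'
#' @param control,treated `cohort_trajectory` objects from [run_cohort()];
#'   `treated` must carry the intervention.
#' @param wtp Willingness to pay per QALY, SEK.
#' @param horizons Horizons for NNT reporting.
#' @return An object of class `cea_result`.
#' @export
compare_arms <- function(control, treated, wtp = 600000,
                         horizons = c(10, 20, 30, 40)) {
  stopifnot(inherits(control, "cohort_trajectory"),
            inherits(treated, "cohort_trajectory"))
  if (max(control$cycles$cycle) != max(treated$cycles$cycle)) {
    stop_param("control and treated trajectories have different horizons")
  }
  spec <- treated$intervention
  N <- control$inputs$n_cohort
  horizons <- unique(pmin(horizons, max(control$cycles$cycle)))
  s0 <- summarize_trajectory(control, horizons = max(control$cycles$cycle))
  s1 <- summarize_trajectory(treated, horizons = max(treated$cycles$cycle))
  cost0 <- (s0$cost_total + s0$cost_treatment) / N
  cost1 <- (s1$cost_total + s1$cost_treatment) / N
  q0 <- s0$qaly_total / N
  q1 <- s1$qaly_total / N
  core <- cea_from_npv(cost0, cost1, q0, q1, wtp = wtp)

  nnt <- map_df(horizons, function(h) {
    a0 <- summarize_trajectory(control, h)$cum_dementia_cases
    a1 <- summarize_trajectory(treated, h)$cum_dementia_cases
    tibble(horizon = h, avoided_cases = a0 - a1,
           nnt = compute_nnt(N, a0 - a1))
  })

  d_py <- tibble(
    state = living_states,
    control = unlist(s0[paste0("py_per_person_",
                               tolower(living_states))], use.names = FALSE),
    treated = unlist(s1[paste0("py_per_person_",
                               tolower(living_states))], use.names = FALSE)
  ) |> mutate(delta = .data$treated - .data$control)
  d_py_total <- s1$py_per_person - s0$py_per_person
  d_py_mci <- s1$py_per_person_mci - s0$py_per_person_mci

  tx_py_disc <- sum(treated$cycles$treated_py_disc) / N
  price <- if (is.null(spec)) 0 else spec$annual_cost
  dc0 <- core$delta_cost - price * tx_py_disc   # increment at price 0
  thresholds <- c(
    budget_neutral = if (tx_py_disc > 0) -dc0 / tx_py_disc else NA_real_,
    nmb_zero = if (tx_py_disc > 0) (wtp * core$delta_qaly - dc0) / tx_py_disc
               else NA_real_
  )

  structure(list(
    per_person = tibble(arm = c("control", "treated"),
                        cost = c(cost0, cost1), qaly = c(q0, q1)),
    delta_cost = core$delta_cost, delta_qaly = core$delta_qaly,
    icer = core$icer, icer_defined = core$icer_defined, nmb = core$nmb,
    wtp = wtp, nnt = nnt, delta_py = d_py,
    delta_py_total = d_py_total,
    cost_per_dementia_free_py = if (abs(d_py_mci) > 1e-12)
      core$delta_cost / d_py_mci else NA_real_,
    cost_per_prolonged_py = if (abs(d_py_total) > 1e-12)
      core$delta_cost / d_py_total else NA_real_,
    treated_py_disc = tx_py_disc, price = price,
    threshold_prices = thresholds,
    epidemiology = tibble(
      measure = c("cum_dementia_cases", "cum_deaths",
                  "cum_deaths_dementia", "cum_deaths_mci"),
      control = c(s0$cum_dementia_cases, s0$cum_deaths,
                  s0$cum_deaths_dementia, s0$cum_deaths_mci),
      treated = c(s1$cum_dementia_cases, s1$cum_deaths,
                  s1$cum_deaths_dementia, s1$cum_deaths_mci)
    ) |> mutate(delta = .data$treated - .data$control)
  ), class = "cea_result")
}

#' Threshold treatment price
#'
#' The incremental cost is affine in the annual treatment price (price
#' enters only through discounted treated person-years), so the
#' budget-neutral price (incremental cost 0) and the price at which
#' NMB(wtp) = 0 are solved in closed form from one evaluated comparison.
#'
#' @param result A [compare_arms()] result.
#' @param target `"budget_neutral"` or `"nmb_zero"`.
#' @param wtp Willingness to pay used for `"nmb_zero"`; defaults to the one
#'   stored in `result`.
#' @return Threshold price, SEK per treated person-year.
#' @export
threshold_price <- function(result, target = c("budget_neutral", "nmb_zero"),
                            wtp = NULL) {
  stopifnot(inherits(result, "cea_result"))
  target <- match.arg(target)
  T <- result$treated_py_disc
  if (T <= 0) return(NA_real_)
  dc0 <- result$delta_cost - result$price * T
  if (target == "budget_neutral") -dc0 / T
  else {
    wtp <- wtp %||% result$wtp
    (wtp * result$delta_qaly - dc0) / T
  }
}

#' One-way scenario battery
#'
#' Runs control and treated arms for the base case and a set of named
#' scenario overrides, returning one result row per scenario. Valid knobs:
#' `rrr` (0.25 / 0.5 / 1.0 ...), `treated_states`, `treatment_cost`,
#' `start_age` (with `horizon`), `horizon`, `risk_decline` (time-dependent
#' progression), `low_mortality` (`TRUE` uses the direct-Weibull mortality
#' in `mortality_low`), `no_backward`, `discount_rate`.
#'
#' @param inputs Base [model_inputs()].
#' @param intervention Base [intervention_spec()].
#' @param scenarios Named list of named override lists (may be empty).
#' @param wtp Willingness to pay, SEK per QALY.
#' @param mortality_low Optional low-mortality `mortality_model` used when a
#'   scenario sets `low_mortality = TRUE`.
#' @return A tibble with one row per scenario (base case first): incremental
#'   cost, QALYs, ICER, NMB, avoided cases, NNT at the final horizon, and
#'   per-arm totals.
#' @export
scenario_battery <- function(inputs, intervention, scenarios = list(),
                             wtp = 600000, mortality_low = NULL) {
  valid <- c("rrr", "treated_states", "treatment_cost", "start_age",
             "horizon", "risk_decline", "low_mortality", "no_backward",
             "discount_rate")
  all_sc <- c(list(base = list()), scenarios)
  map_df(names(all_sc), function(nm) {
    ov <- all_sc[[nm]]
    bad <- setdiff(names(ov), valid)
    if (length(bad)) {
      stop_param("unknown scenario knob(s) %s; valid: %s",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", "))
    }
    inp <- inputs
    spec <- intervention
    if (!is.null(ov$rrr)) spec$rrr <- ov$rrr
    if (!is.null(ov$treated_states)) spec$treated_states <- ov$treated_states
    if (!is.null(ov$treatment_cost)) spec$annual_cost <- ov$treatment_cost
    if (!is.null(ov$start_age)) {
      inp$start_age <- ov$start_age
      spec$start_age <- ov$start_age
    }
    if (!is.null(ov$horizon)) inp$horizon <- as.integer(ov$horizon)
    if (!is.null(ov$risk_decline)) inp$risk_decline <- ov$risk_decline
    if (!is.null(ov$discount_rate)) inp$discount_rate <- ov$discount_rate
    if (!is.null(ov$no_backward)) inp$no_backward <- ov$no_backward
    if (isTRUE(ov$low_mortality)) {
      if (is.null(mortality_low)) stop_param("no `mortality_low` model supplied")
      inp$mortality <- mortality_low
    }
    ctrl <- run_cohort(inp)
    trt <- run_cohort(inp, intervention = spec)
    res <- compare_arms(ctrl, trt, wtp = wtp, horizons = inp$horizon)
    tibble(scenario = nm,
           delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
           icer = res$icer, nmb = res$nmb,
           avoided_cases = res$nnt$avoided_cases[nrow(res$nnt)],
           nnt = res$nnt$nnt[nrow(res$nnt)],
           cost_control = res$per_person$cost[1],
           cost_treated = res$per_person$cost[2],
           qaly_control = res$per_person$qaly[1],
           qaly_treated = res$per_person$qaly[2])
  })
}
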