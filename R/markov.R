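#' Convert a multi-year risk to an annual risk
#'
#' Constant-rate annualization: `p_1 = 1 - (1 - p_multi)^(1/years)`.
#' The base-case 3-year AD-MCI to AD-dementia progression risk of 50%
#' becomes an annual risk of 20.6%.
#'
#' @param p_multi Cumulative risk over `years` years, in `[0, 1]`.
#' @param years Length of the original risk window, > 0.
#' @return Annual risk.
#' @examples
#' annualize_risk(0.50, 3)  # 0.2063
#' @export
annualize_risk <- function(p_multi, years) {
  check_prob(p_multi, "p_multi")
  if (any(years <= 0)) stop_domain("`years` must be positive")
  1 - (1 - p_multi)^(1 / years)
}

#' Time-dependent annual progression risk
#'
#' Sensitivity scenario in which the annual progression risk declines by a
#' relative fraction `d` for each year in the model:
#' `risk_k = base * (1 - d)^(k - 1)`.
#'
#' @param base Annual risk in cycle 1.
#' @param d Relative decline per year, in `[0, 1)`.
#' @param cycle Model cycle (1-based).
#' @return Risk in the given cycle.
#' @examples
#' time_dependent_risk(0.206, 0.10, 2)  # 0.1854
#' @export
time_dependent_risk <- function(base, d, cycle) {
  check_prob(base, "base")
  if (any(d < 0 | d >= 1)) stop_domain("`d` must be in [0, 1)")
  if (any(cycle < 1)) stop_domain("`cycle` must be >= 1")
  base * (1 - d)^(cycle - 1)
}

#' Discount factor
#'
#' `(1 + r)^(-t)`. Accruals of cycle `t` are discounted at exponent `t`
#' (end-anchored grid with half-cycle-averaged occupancy); a mid-cycle
#' exponent `t - 0.5` is available via `midcycle = TRUE`.
#'
#' @param r Discount rate, >= 0.
#' @param t Cycle index, >= 0.
#' @param midcycle Use exponent `t - 0.5`.
#' @return Discount factor.
#' @export
discount_factor <- function(r, t, midcycle = FALSE) {
  if (any(r < 0)) stop_domain("`r` must be >= 0")
  if (any(t < 0)) stop_domain("`t` must be >= 0")
  (1 + r)^(-(t - if (midcycle) 0.5 else 0))
}

#' Assemble the input bundle for the cohort engine
#'
#' @param n_cohort Cohort size (default 100,000).
#' @param start_age Age at model start (default 60).
#' @param start_state State the cohort starts in (default `"MCI"`).
#' @param horizon Number of annual cycles (default 40).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param annual_risk Annual AD-MCI to AD-dementia progression risk
#'   (default `annualize_risk(0.50, 3)`, i.e. 20.6%).
#' @param risk_decline Relative annual decline of the progression risk
#'   (0 = constant risk base case).
#' @param dementia_matrix Either a 3x4 row-stochastic matrix (rows Mild,
#'   Moderate, Severe; columns MCI, Mild, Moderate, Severe; MCI column 0) of
#'   one-year transitions between living states, or a fitted
#'   [fit_ordered_probit()] `transition_model` (matrices are then derived per
#'   age group and any mass on MCI is removed and renormalized, since
#'   dementia cannot revert to MCI).
#' @param mortality A `mortality_model` (hazard ratios on the life table, or
#'   the direct-Weibull low-mortality variant).
#' @param life_table Life table tibble (`age`, `q`).
#' @param costs Named annual state costs (SEK/year) for MCI, Mild, Moderate,
#'   Severe, or a fitted [fit_cost_glm()] `cost_model`.
#' @param cost_age_coef Log-linear age adjustment of vector costs
#'   (0 = flat; ignored for a fitted cost model, which carries its own).
#' @param utilities A [utility_model()].
#' @param no_backward Redistribute backward (toward less severe) transition
#'   mass to the diagonal (sensitivity scenario).
#' @param death_method Passed to [death_probability()].
#' @return A list of class `model_inputs`.
#' @export
model_inputs <- function(n_cohort = 100000, start_age = 60,
                         start_state = "MCI",
                         horizon = 40, discount_rate = 0.03,
                         annual_risk = annualize_risk(0.50, 3),
                         risk_decline = 0,
                         dementia_matrix,
                         mortality,
                         life_table,
                         costs,
                         cost_age_coef = 0,
                         utilities = utility_model(),
                         no_backward = FALSE,
                         death_method = "probability") {
  if (n_cohort <= 0) stop_param("`n_cohort` must be positive")
  if (horizon < 1) stop_param("`horizon` must be >= 1")
  if (discount_rate < 0) stop_param("`discount_rate` must be >= 0")
  check_prob(annual_risk, "annual_risk")
  if (!start_state %in% living_states) stop_param("invalid `start_state`")
  validate_life_table(life_table)
  if (is.matrix(dementia_matrix)) {
    stopifnot(nrow(dementia_matrix) == 3, ncol(dementia_matrix) == 4)
    if (any(dementia_matrix < 0) ||
        any(abs(rowSums(dementia_matrix) - 1) > 1e-9)) {
      stop_param("`dementia_matrix` rows must be non-negative and sum to 1")
    }
    dimnames(dementia_matrix) <- list(dementia_states, living_states)
  } else if (!inherits(dementia_matrix, "transition_model")) {
    stop_param("`dementia_matrix` must be a matrix or a transition_model")
  }
  stopifnot(inherits(mortality, "mortality_model"),
            inherits(utilities, "utility_model"))
  structure(list(
    n_cohort = n_cohort, start_age = start_age, start_state = start_state,
    horizon = as.integer(horizon), discount_rate = discount_rate,
    annual_risk = annual_risk, risk_decline = risk_decline,
    dementia_matrix = dementia_matrix, mortality = mortality,
    life_table = life_table, costs = costs, cost_age_coef = cost_age_coef,
    utilities = utilities, no_backward = no_backward,
    death_method = death_method
  ), class = "model_inputs")
}

# dementia rows (Mild/Moderate/Severe over living states) at an age
dementia_rows <- function(inputs, age) {
  if (is.matrix(inputs$dementia_matrix)) {
    m <- inputs$dementia_matrix
  } else {
    tm <- transition_matrix(inputs$dementia_matrix, age75 = age >= 75)
    m <- matrix(0, 3, 4, dimnames = list(dementia_states, living_states))
    for (s in dementia_states) {
      for (t in intersect(colnames(tm), living_states)) m[s, t] <- tm[s, t]
    }
    m[, "MCI"] <- 0                      # no reversal to MCI
    m <- m / rowSums(m)
  }
  if (inputs$no_backward) {
    for (i in seq_len(3)) {
      diag_col <- i + 1L                 # column of own state
      back <- seq_len(diag_col - 1L)
      m[i, diag_col] <- m[i, diag_col] + sum(m[i, back])
      m[i, back] <- 0
    }
  }
  m
}

#' Full 5x5 one-cycle transition matrix
#'
#' Composes the living-state transition structure (MCI may move only to
#' Mild or stay; dementia states follow the dementia matrix) with mortality:
#' the death column comes from [death_probability()] at the given age, and
#' living-state probabilities are rescaled to `1 - p_death`. The Death row
#' is absorbing.
#'
#' @param inputs A [model_inputs()] bundle.
#' @param age Age of the cohort during the cycle.
#' @param cycle Cycle index (1-based; drives the time-dependent risk).
#' @param intervention Optional [intervention_spec()] applied to treated
#'   states in the treatment window.
#' @return A 5x5 row-stochastic matrix over MCI, Mild, Moderate, Severe,
#'   Death.
#' @export
build_transition_matrix <- function(inputs, age, cycle, intervention = NULL) {
  p_prog <- time_dependent_risk(inputs$annual_risk, inputs$risk_decline, cycle)
  living <- matrix(0, 4, 4, dimnames = list(living_states, living_states))
  living["MCI", "MCI"] <- 1 - p_prog
  living["MCI", "Mild"] <- p_prog
  living[dementia_states, ] <- dementia_rows(inputs, age)

  p_death <- state_death_probs(inputs$mortality, inputs$life_table, age,
                               method = inputs$death_method)
  full <- matrix(0, 5, 5, dimnames = list(model_states, model_states))
  full[living_states, living_states] <- living * (1 - p_death)
  full[living_states, "Death"] <- p_death
  full["Death", "Death"] <- 1

  if (!is.null(intervention)) {
    for (s in treated_now(intervention, age, cycle)) {
      full[s, ] <- apply_intervention(full[s, ], s, intervention)
    }
  }
  if (any(full < -1e-12)) {
    abort("negative transition probability after composition",
          class = "admarkov_internal_error")
  }
  if (any(abs(rowSums(full) - 1) > 1e-12)) {
    abort("transition matrix rows do not sum to 1",
          class = "admarkov_internal_error")
  }
  full
}

#' Run the Markov cohort simulation
#'
#' Deterministic matrix propagation of the cohort occupancy vector over the
#' horizon. Person-years, costs and QALYs accrue per cycle with half-cycle
#' correction (the average of beginning- and end-of-cycle occupancy) and are
#' discounted to net present values at exponent equal to the cycle index.
#' Incident dementia accumulates the MCI to Mild flow; deaths are split by
#' the state they occurred from. When an intervention is supplied, its
#' annual cost accrues per (half-cycle-corrected, discounted) person-year
#' spent in a treated state inside the treatment window.
#'
#' @param inputs A [model_inputs()] bundle.
#' @param intervention Optional [intervention_spec()].
#' @return An object of class `cohort_trajectory`: a list with `cycles`
#'   (one tibble row per cycle with occupancy, flows, person-years, and
#'   discounted cost/QALY streams by state), the initial occupancy, and the
#'   inputs used.
#' @export
run_cohort <- function(inputs, intervention = NULL) {
  stopifnot(inherits(inputs, "model_inputs"))
  if (inputs$horizon < 1) stop_param("horizon must be >= 1")
  N <- inputs$n_cohort
  r <- inputs$discount_rate
  x <- setNames(numeric(5), model_states)
  x[inputs$start_state] <- N

  H <- inputs$horizon
  occ <- matrix(0, H, 5); py_m <- matrix(0, H, 4)
  deaths_m <- matrix(0, H, 4); cost_m <- matrix(0, H, 4)
  qaly_m <- matrix(0, H, 4)
  incident <- disc_v <- tx_py_v <- tx_cost_v <- numeric(H)
  for (t in seq_len(H)) {
    age <- inputs$start_age + t - 1
    M <- build_transition_matrix(inputs, age, t, intervention)
    x_new <- drop(x %*% M)
    deaths_m[t, ] <- x[living_states] * M[living_states, "Death"]
    incident[t] <- x[["MCI"]] * M["MCI", "Mild"]
    py <- (x[living_states] + x_new[living_states]) / 2
    disc <- discount_factor(r, t)

    cvec <- state_costs(inputs, age)
    uvec <- utility_value(age, living_states, inputs$utilities)
    tx_py <- 0
    if (!is.null(intervention)) {
      st <- treated_now(intervention, age, t)
      tx_py <- sum(py[st])
    }
    occ[t, ] <- x_new
    py_m[t, ] <- py
    cost_m[t, ] <- py * cvec * disc
    qaly_m[t, ] <- py * uvec * disc
    disc_v[t] <- disc
    tx_py_v[t] <- tx_py
    tx_cost_v[t] <- if (is.null(intervention)) 0 else
      tx_py * intervention$annual_cost * disc
    x <- x_new
  }
  cycles <- tibble(cycle = seq_len(H),
                   age = inputs$start_age + seq_len(H) - 1,
                   discount = disc_v)
  for (j in 1:5) cycles[[paste0("occ_", model_states[j])]] <- occ[, j]
  for (j in 1:4) cycles[[paste0("py_", living_states[j])]] <- py_m[, j]
  for (j in 1:4) cycles[[paste0("deaths_from_", living_states[j])]] <- deaths_m[, j]
  cycles$incident_dementia <- incident
  for (j in 1:4) cycles[[paste0("cost_", living_states[j])]] <- cost_m[, j]
  for (j in 1:4) cycles[[paste0("qaly_", living_states[j])]] <- qaly_m[, j]
  cycles$treated_py <- tx_py_v
  cycles$treated_py_disc <- tx_py_v * disc_v
  cycles$cost_treatment <- tx_cost_v
  structure(list(
    cycles = cycles,
    initial = setNames(c(N * (inputs$start_state == model_states)), model_states),
    inputs = inputs, intervention = intervention
  ), class = "cohort_trajectory")
}

# per-state annual cost vector at an age
state_costs <- function(inputs, age) {
  if (inherits(inputs$costs, "cost_model")) {
    setNames(predict_cost(inputs$costs, rep(age, 4), living_states),
             living_states)
  } else {
    inputs$costs[living_states] * exp(inputs$cost_age_coef * (age - 77))
  }
}

#' Summarize a cohort trajectory at one or more horizons
#'
#' Cumulative dementia cases, deaths (total and by state at death), mean
#' person-years per person overall and by state, cumulative discounted costs
#' and QALYs by state, and the discounted cost per person-year lived with
#' dementia.
#'
#' @param trajectory A [run_cohort()] result.
#' @param horizons Horizons (years) to report; defaults to 10/20/30/40
#'   truncated to the run's horizon.
#' @return A tibble with one row per horizon.
#' @export
summarize_trajectory <- function(trajectory, horizons = c(10, 20, 30, 40)) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  cy <- trajectory$cycles
  N <- trajectory$inputs$n_cohort
  horizons <- horizons[horizons <= max(cy$cycle)]
  map_df(horizons, function(h) {
    d <- cy[cy$cycle <= h, ]
    last <- d[nrow(d), ]
    py <- colSums(d[paste0("py_", living_states)])
    cost <- colSums(d[paste0("cost_", living_states)])
    qaly <- colSums(d[paste0("qaly_", living_states)])
    deaths <- colSums(d[paste0("deaths_from_", living_states)])
    dem_py <- sum(py[paste0("py_", dementia_states)])
    tibble(
      horizon = h,
      cum_dementia_cases = sum(d$incident_dementia),
      cum_deaths = sum(deaths),
      cum_deaths_dementia = sum(deaths[paste0("deaths_from_", dementia_states)]),
      cum_deaths_mci = deaths[["deaths_from_MCI"]],
      py_per_person = sum(py) / N,
      py_per_person_mci = py[["py_MCI"]] / N,
      py_per_person_mild = py[["py_Mild"]] / N,
      py_per_person_moderate = py[["py_Moderate"]] / N,
      py_per_person_severe = py[["py_Severe"]] / N,
      py_per_person_dementia = dem_py / N,
      cost_mci = cost[["cost_MCI"]],
      cost_mild = cost[["cost_Mild"]],
      cost_moderate = cost[["cost_Moderate"]],
      cost_severe = cost[["cost_Severe"]],
      cost_total = sum(cost),
      cost_treatment = sum(d$cost_treatment),
      qaly_mci = qaly[["qaly_MCI"]],
      qaly_mild = qaly[["qaly_Mild"]],
      qaly_moderate = qaly[["qaly_Moderate"]],
      qaly_severe = qaly[["qaly_Severe"]],
      qaly_total = sum(qaly),
      cost_per_dementia_py = cost_per_dementia_py(
        sum(cost[paste0("cost_", dementia_states)]), dem_py),
      survivors = N - sum(deaths)
    )
  })
}

#' Discounted cost per person-year lived with dementia
#'
#' @param dementia_cost Total (discounted) cost accrued in the dementia
#'   states, SEK.
#' @param dementia_py Total person-years lived in the dementia states.
#' @return SEK per person-year (NA if no dementia person-years).
#' @export
cost_per_dementia_py <- function(dementia_cost, dementia_py) {
  if (dementia_py <= 0) return(NA_real_)
  dementia_cost / dementia_py
}
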