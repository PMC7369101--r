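#' Specify a probabilistic sensitivity analysis
#'
#' Parameters are drawn independently around their base-case means with a
#' standard error of 25% of the mean (configurable): gamma distributions
#' for costs (treatment price and state costs), beta distributions
#' (moment-matched; SE truncated if the implied beta is infeasible) for
#' probabilities and utilities, and gamma for the positive scaling factors
#' on within-dementia progression and mortality. Age-varying inputs are
#' frozen at their values for a fixed reference age (71 by default) for the
#' PSA runs only.
#'
#' @param inputs Base [model_inputs()].
#' @param intervention Base [intervention_spec()].
#' @param n_iter Number of iterations (default 1,000).
#' @param se_frac Standard error as a fraction of the mean (default 0.25).
#' @param age_ref Reference age at which age-varying inputs are frozen.
#' @param lambda_grid Willingness-to-pay grid for the acceptability curve.
#' @param prob_dist Distribution for probability-domain parameters:
#'   `"beta"` (default) or `"logitnormal"`.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(inputs, intervention, n_iter = 1000, se_frac = 0.25,
                     age_ref = 71,
                     lambda_grid = seq(0, 1200000, by = 50000),
                     prob_dist = c("beta", "logitnormal")) {
  prob_dist <- match.arg(prob_dist)
  if (n_iter < 1) stop_param("`n_iter` must be >= 1")
  if (se_frac <= 0) stop_param("`se_frac` must be positive")
  if (inherits(inputs$costs, "cost_model")) {
    cost_means <- setNames(predict_cost(inputs$costs, rep(age_ref, 4),
                                        living_states), living_states)
  } else {
    cost_means <- state_costs(inputs, age_ref)
  }
  u_means <- setNames(utility_value(age_ref, living_states,
                                    inputs$utilities), living_states)
  means <- c(
    list(treatment_cost = intervention$annual_cost,
         annual_risk = inputs$annual_risk,
         progression_scale = 1,
         mortality_scale = 1),
    as.list(setNames(cost_means, paste0("cost_", living_states))),
    as.list(setNames(u_means, paste0("utility_", living_states)))
  )
  if (means$treatment_cost <= 0) {
    stop_param("gamma-distributed treatment cost needs a positive mean")
  }
  structure(list(inputs = inputs, intervention = intervention,
                 n_iter = as.integer(n_iter), se_frac = se_frac,
                 age_ref = age_ref, lambda_grid = lambda_grid,
                 prob_dist = prob_dist, means = means),
            class = "psa_spec")
}

rgamma_mean_se <- function(n, mean, se) {
  if (mean <= 0) stop_param("gamma parameter needs a positive mean")
  if (se == 0) return(rep(mean, n))
  shape <- (mean / se)^2
  rgamma(n, shape = shape, scale = se^2 / mean)
}

rprob_mean_se <- function(n, mean, se, dist = "beta") {
  if (se == 0) return(rep(mean, n))
  if (dist == "logitnormal") {
    mu <- qlogis(mean)
    sdl <- se / (mean * (1 - mean))   # delta method on the logit scale
    return(plogis(rnorm(n, mu, sdl)))
  }
  vmax <- mean * (1 - mean)
  if (se^2 >= vmax) se <- 0.95 * sqrt(vmax)  # truncate infeasible SE
  f <- vmax / se^2 - 1
  rbeta(n, shape1 = mean * f, shape2 = (1 - mean) * f)
}

#' Draw one PSA parameter set
#'
#' Reproducible under (seed, iteration index): the RNG is re-seeded from
#' both before drawing.
#'
#' @param spec A [psa_spec()].
#' @param iteration Iteration index (1-based).
#' @param seed Base seed.
#' @return A named list of drawn parameter values.
#' @export
draw_parameters <- function(spec, iteration, seed = 1) {
  stopifnot(inherits(spec, "psa_spec"))
  set.seed((seed %% 1000000L) * 2000L + iteration)
  m <- spec$means
  sf <- spec$se_frac
  draw_gamma <- function(mean) rgamma_mean_se(1, mean, sf * mean)
  draw_prob <- function(mean) rprob_mean_se(1, mean, sf * mean, spec$prob_dist)
  out <- list(
    treatment_cost = draw_gamma(m$treatment_cost),
    annual_risk = draw_prob(m$annual_risk),
    progression_scale = draw_gamma(m$progression_scale),
    mortality_scale = draw_gamma(m$mortality_scale)
  )
  for (s in living_states) {
    out[[paste0("cost_", s)]] <- draw_gamma(m[[paste0("cost_", s)]])
    out[[paste0("utility_", s)]] <- draw_prob(m[[paste0("utility_", s)]])
  }
  out
}

# inputs with age-varying pieces frozen at age_ref and draws applied
psa_iteration_inputs <- function(spec, draw) {
  inp <- spec$inputs
  q_ref <- min(1, lookup_q(inp$life_table, spec$age_ref) * draw$mortality_scale)
  inp$life_table <- tibble(age = inp$life_table$age,
                           q = rep(q_ref, nrow(inp$life_table)))
  inp$annual_risk <- min(draw$annual_risk, 0.999)
  # freeze the dementia transition structure at the reference age (for a
  # fitted transition model this picks the matrix of age_ref's age group)
  dm <- dementia_rows(inp, spec$age_ref)
  # scale forward progression within dementia, freed/extra mass to diagonal
  sc <- draw$progression_scale
  for (i in seq_len(3)) {
    diag_col <- i + 1L
    fwd <- which(seq_len(4) > diag_col)
    if (!length(fwd)) next
    avail <- dm[i, diag_col] + sum(dm[i, fwd])
    newf <- pmin(dm[i, fwd] * sc, dm[i, fwd] / sum(dm[i, fwd]) * avail)
    dm[i, diag_col] <- dm[i, diag_col] + sum(dm[i, fwd]) - sum(newf)
    dm[i, fwd] <- newf
  }
  inp$dementia_matrix <- dm
  inp$costs <- setNames(vapply(living_states, function(s)
    draw[[paste0("cost_", s)]], numeric(1)), living_states)
  inp$cost_age_coef <- 0
  u <- vapply(living_states, function(s) draw[[paste0("utility_", s)]],
              numeric(1))
  inp$utilities <- structure(
    list(slope = 0, intercept = u[["MCI"]],
         decrements = u[["MCI"]] - u, age_offset = 0),
    class = "utility_model")
  inp
}

#' Run the probabilistic sensitivity analysis
#'
#' For each iteration, draws one parameter set (shared by both arms), runs
#' control and treated cohorts at the frozen reference-age operating point,
#' and records the per-person incremental cost and QALYs. Reports the
#' probability of cost-effectiveness at the willingness to pay and the full
#' acceptability curve over the lambda grid. Iterations that fail are
#' recorded, excluded and counted.
#'
#' @param spec A [psa_spec()].
#' @param seed Base seed.
#' @param wtp Willingness to pay for the headline probability, SEK.
#' @return An object of class `psa_result` with `iterations` (tibble:
#'   `iteration`, `delta_cost`, `delta_qaly`), `ceac` (tibble: `lambda`,
#'   `prob_ce`), `prob_ce_wtp`, `wtp`, `n_failed`.
#' @export
run_psa <- function(spec, seed = 1, wtp = 600000) {
  stopifnot(inherits(spec, "psa_spec"))
  rows <- vector("list", spec$n_iter)
  n_failed <- 0L
  for (i in seq_len(spec$n_iter)) {
    res <- tryCatch({
      draw <- draw_parameters(spec, i, seed = seed)
      inp <- psa_iteration_inputs(spec, draw)
      iv <- spec$intervention
      iv$annual_cost <- draw$treatment_cost
      ctrl <- run_cohort(inp)
      trt <- run_cohort(inp, intervention = iv)
      N <- inp$n_cohort
      tot <- function(tr, what) {
        sum(unlist(tr$cycles[paste0(what, "_", living_states)]))
      }
      tibble(iteration = i,
             delta_cost = (tot(trt, "cost") + sum(trt$cycles$cost_treatment) -
                             tot(ctrl, "cost") - sum(ctrl$cycles$cost_treatment)) / N,
             delta_qaly = (tot(trt, "qaly") - tot(ctrl, "qaly")) / N)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[i]] <- res
  }
  if (n_failed > 0) {
    warn(sprintf("%d PSA iteration(s) failed and were excluded", n_failed))
  }
  iterations <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(iterations) == 0) {
    abort("all PSA iterations failed", class = "admarkov_fit_error")
  }
  curve <- ceac_curve(iterations, spec$lambda_grid)
  structure(list(iterations = iterations, ceac = curve,
                 prob_ce_wtp = mean(wtp * iterations$delta_qaly -
                                      iterations$delta_cost > 0),
                 wtp = wtp, n_failed = n_failed,
                 lambda_grid = spec$lambda_grid),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations with
#' positive net monetary benefit (`lambda * dQ - dC > 0`; exact ties count
#' as not cost-effective).
#'
#' @param iterations Tibble with `delta_cost` and `delta_qaly` per
#'   iteration, or a `psa_result`.
#' @param lambda_grid Willingness-to-pay grid.
#' @return A tibble with columns `lambda` and `prob_ce`.
#' @export
ceac_curve <- function(iterations, lambda_grid = seq(0, 1200000, by = 50000)) {
  if (inherits(iterations, "psa_result")) iterations <- iterations$iterations
  if (nrow(iterations) == 0) abort("need at least one successful iteration")
  tibble(lambda = lambda_grid,
         prob_ce = vapply(lambda_grid, function(l)
           mean(l * iterations$delta_qaly - iterations$delta_cost > 0),
           numeric(1)))
}
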