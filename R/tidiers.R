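#' Tidy a cohort trajectory into long format
#'
#' @param x A `cohort_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `age`, `state`, `occupancy`,
#'   `person_years`, `cost`, `qaly` (costs/QALYs discounted; person-years
#'   not; Death rows carry occupancy only).
#' @exportS3Method generics::tidy
tidy.cohort_trajectory <- function(x, ...) {
  cy <- x$cycles
  long <- map_df(model_states, function(s) {
    tibble(cycle = cy$cycle, age = cy$age, state = s,
           occupancy = cy[[paste0("occ_", s)]],
           person_years = if (s == "Death") NA_real_ else cy[[paste0("py_", s)]],
           cost = if (s == "Death") NA_real_ else cy[[paste0("cost_", s)]],
           qaly = if (s == "Death") NA_real_ else cy[[paste0("qaly_", s)]])
  })
  long$state <- factor(long$state, levels = model_states)
  arrange(long, .data$cycle, .data$state)
}

#' @exportS3Method generics::glance
glance.cohort_trajectory <- function(x, ...) {
  s <- summarize_trajectory(x, horizons = max(x$cycles$cycle))
  N <- x$inputs$n_cohort
  tibble(horizon = s$horizon,
         n_cohort = N,
         cum_dementia_cases = s$cum_dementia_cases,
         cum_deaths = s$cum_deaths,
         py_per_person = s$py_per_person,
         cost_per_person = (s$cost_total + s$cost_treatment) / N,
         qaly_per_person = s$qaly_total / N,
         cost_per_dementia_py = s$cost_per_dementia_py)
}

#' @exportS3Method generics::tidy
tidy.cea_result <- function(x, ...) {
  tibble(measure = c("delta_cost", "delta_qaly", "icer", "nmb",
                     "cost_per_dementia_free_py", "cost_per_prolonged_py",
                     "threshold_price_budget_neutral",
                     "threshold_price_nmb_zero"),
         value = c(x$delta_cost, x$delta_qaly, x$icer, x$nmb,
                   x$cost_per_dementia_free_py, x$cost_per_prolonged_py,
                   x$threshold_prices[["budget_neutral"]],
                   x$threshold_prices[["nmb_zero"]]))
}

#' @exportS3Method generics::glance
glance.cea_result <- function(x, ...) {
  tibble(delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
         icer = x$icer, nmb = x$nmb, wtp = x$wtp,
         nnt_final = x$nnt$nnt[nrow(x$nnt)],
         avoided_cases_final = x$nnt$avoided_cases[nrow(x$nnt)])
}

#' @exportS3Method generics::tidy
tidy.psa_result <- function(x, ...) x$iterations

#' @exportS3Method generics::glance
glance.psa_result <- function(x, ...) {
  tibble(n_iter = nrow(x$iterations), n_failed = x$n_failed,
         prob_ce_wtp = x$prob_ce_wtp, wtp = x$wtp,
         mean_delta_cost = mean(x$iterations$delta_cost),
         mean_delta_qaly = mean(x$iterations$delta_qaly))
}

#' @exportS3Method generics::tidy
tidy.transition_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Value"],
         std.error = s[, "Std. Error"],
         type = c(rep("coefficient", length(x$coefficients)),
                  rep("cutpoint", length(x$cutpoints))))
}

#' @exportS3Method generics::tidy
tidy.mortality_model <- function(x, ...) {
  tibble(term = c("shape", "rate", paste0("HR_", names(x$hazard_ratios))),
         estimate = c(x$shape %||% NA_real_, x$rate %||% NA_real_,
                      unname(x$hazard_ratios)))
}

#' @exportS3Method generics::tidy
tidy.cost_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cohort_trajectory> %d cycles, cohort %s, start age %d%s\n",
              max(x$cycles$cycle), format(x$inputs$n_cohort, big.mark = ","),
              x$inputs$start_age,
              if (is.null(x$intervention)) "" else
                sprintf(" [%s]", x$intervention$id)))
  cat(sprintf("  cumulative dementia %.0f, deaths %.0f, PY/person %.2f\n",
              g$cum_dementia_cases, g$cum_deaths, g$py_per_person))
  cat(sprintf("  NPV cost/person %.0f SEK, QALYs/person %.2f\n",
              g$cost_per_person, g$qaly_per_person))
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  dCost %.0f SEK, dQALY %.4f, ICER %s, NMB(%s) %.0f\n",
              x$delta_cost, x$delta_qaly,
              if (x$icer_defined) sprintf("%.0f", x$icer) else "undefined",
              format(x$wtp, big.mark = ","), x$nmb))
  cat(sprintf("  threshold price: budget-neutral %.0f, NMB=0 %.0f SEK/year\n",
              x$threshold_prices[["budget_neutral"]],
              x$threshold_prices[["nmb_zero"]]))
  invisible(x)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (%d failed)\n",
              nrow(x$iterations), x$n_failed))
  cat(sprintf("  P(cost-effective at %s SEK/QALY) = %.3f\n",
              format(x$wtp, big.mark = ","), x$prob_ce_wtp))
  invisible(x)
}
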