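#' Fit the censoring (drop-out) model
#'
#' Logistic regression of remaining under observation at the next annual
#' grid point, given current severity state and age. Death is an observed
#' outcome, not censoring: only intervals with neither a next status nor a
#' death count as censored.
#'
#' @param transitions Output of [build_transitions()] (rows with
#'   `to_state = NA` are the censored intervals).
#' @param use_age Include age (linear) as a covariate; default `TRUE`.
#' @return An object of class `censoring_model` wrapping the glm fit.
#' @export
fit_censoring_model <- function(transitions, use_age = TRUE) {
  df <- as_tibble(transitions)
  df$continued <- !is.na(df$to_state)
  if (length(unique(df$continued)) < 2) {
    # no censoring at all: degenerate model, continuation probability 1
    fit <- NULL
  } else {
    form <- if (use_age) continued ~ from_state + age else continued ~ from_state
    fit <- glm(form, family = binomial(), data = df)
    if (!fit$converged) abort("censoring model did not converge",
                              class = "admarkov_fit_error")
    if (any(abs(coef(fit)) > 15)) {
      abort(paste0("censoring model shows (quasi-)complete separation; ",
                   "coefficients: ",
                   paste(sprintf("%s=%.1f", names(coef(fit)), coef(fit)),
                         collapse = ", ")),
            class = "admarkov_fit_error")
    }
  }
  structure(list(fit = fit, use_age = use_age,
                 marginal = mean(df$continued)),
            class = "censoring_model")
}

#' @export
predict.censoring_model <- function(object, newdata, ...) {
  if (is.null(object$fit)) return(rep(1, nrow(newdata)))
  p <- predict(object$fit, newdata = newdata, type = "response")
  pmin(pmax(p, 1e-12), 1)
}

#' Inverse-probability-of-censoring weights
#'
#' Attaches IPCW weights to annualized transitions: the weight of a person's
#' k-th interval is the inverse of the cumulative predicted probability of
#' having remained under observation through that interval. With
#' stabilization the numerator is the marginal (covariate-free) continuation
#' probability; weights are optionally truncated at a percentile.
#'
#' @param transitions Output of [build_transitions()].
#' @param model A [fit_censoring_model()] object.
#' @param stabilize Use the marginal continuation product as numerator
#'   (default `TRUE`).
#' @param truncate Percentile at which weights are capped (default 0.99);
#'   `NULL` disables truncation.
#' @return `transitions` with the `weight` column replaced.
#' @export
ipcw_weights <- function(transitions, model, stabilize = TRUE, truncate = 0.99) {
  df <- as_tibble(transitions) |> arrange(.data$person_id, .data$grid_year)
  p <- predict(model, df)
  if (any(p <= 0)) stop_domain("continuation probabilities must be positive")
  # stabilization numerator: marginal continuation in the fitting population
  marg <- if (stabilize) model$marginal else 1
  df$.p <- p
  df <- df |>
    group_by(.data$person_id) |>
    mutate(weight = unname(marg^seq_along(.data$.p) / cumprod(.data$.p))) |>
    ungroup() |>
    select(-".p")
  if (!is.null(truncate)) {
    cap <- quantile(df$weight, truncate, names = FALSE)
    df$weight <- pmin(df$weight, cap)
  }
  df
}

#' Fit the ordered-probit transition model
#'
#' Weighted ordered-probit regression of the one-year-ahead cognitive state
#' on the previous state (indicator coded) and an age >= 75 indicator.
#' Transitions to death are excluded: mortality is modelled separately and
#' overlaid by the cohort engine.
#'
#' @param transitions Transition table (typically after [ipcw_weights()]).
#' @param use_age75 Include the age >= 75 indicator (default `TRUE`).
#' @return An object of class `transition_model` with elements `fit` (the
#'   `MASS::polr` object), `cutpoints`, `coefficients`, `levels`.
#' @export
fit_ordered_probit <- function(transitions, use_age75 = TRUE) {
  df <- as_tibble(transitions) |>
    filter(!is.na(.data$to_state), .data$to_state != "Death") |>
    mutate(to_state = droplevels(factor(.data$to_state,
                                        levels = levels(.data$from_state))),
           from_state = droplevels(.data$from_state),
           age75 = as.integer(.data$age >= 75))
  if (nlevels(df$to_state) < 2) {
    abort("need at least 2 outcome levels to fit an ordered probit",
          class = "admarkov_fit_error")
  }
  form <- if (use_age75) to_state ~ from_state + age75 else to_state ~ from_state
  fit <- suppressWarnings(
    MASS::polr(form, data = df, weights = df$weight, method = "probit",
               Hess = TRUE)
  )
  if (fit$convergence != 0) {
    abort(sprintf("ordered probit did not converge (optim code %d, %d iterations)",
                  fit$convergence, fit$niter[1]),
          class = "admarkov_fit_error")
  }
  structure(list(fit = fit, cutpoints = fit$zeta, coefficients = coef(fit),
                 levels = levels(df$to_state), use_age75 = use_age75),
            class = "transition_model")
}

#' One-year transition matrix implied by a fitted transition model
#'
#' @param model A [fit_ordered_probit()] object.
#' @param age75 Logical: matrix for the age >= 75 group?
#' @return A row-stochastic matrix over the ordered living states
#'   (rows = previous state, columns = next state).
#' @export
transition_matrix <- function(model, age75 = FALSE) {
  stopifnot(inherits(model, "transition_model"))
  lev <- model$levels
  nd <- data.frame(from_state = factor(lev, levels = lev),
                   age75 = as.integer(age75))
  p <- predict(model$fit, newdata = nd, type = "probs")
  p <- matrix(p, nrow = length(lev), dimnames = list(from = lev, to = lev))
  p / rowSums(p)
}

#' Counting-process survival records from annualized data
#'
#' One row per person-year at risk, on the age time-scale (left truncated at
#' the interval's entry age): entry age, exit age (death within the year, or
#' censoring one year after the grid point), event flag and the severity
#' state at the interval start.
#'
#' @param annualized Output of [annualize_registry()].
#' @param scheme Staging scheme; `"4level"` (default) keeps Very mild as the
#'   mortality reference level.
#' @return A tibble with columns `person_id`, `entry_age`, `exit_age`,
#'   `event`, `state`.
#' @export
survival_records <- function(annualized, scheme = c("4level", "3level")) {
  scheme <- match.arg(scheme)
  tr <- build_transitions(annualized, scheme = scheme)
  ann <- annualized |> distinct(.data$person_id, .data$grid_year,
                                .data$death_date, .data$baseline_date)
  df <- tr |> left_join(ann, by = c("person_id", "grid_year"))
  exit <- df$age + 1
  event <- !is.na(df$to_state) & df$to_state == "Death"
  if (any(event)) {
    tdeath <- as.numeric(df$death_date[event] -
                           (df$baseline_date[event] +
                              df$grid_year[event] * YEAR_DAYS)) / YEAR_DAYS
    exit[event] <- df$age[event] + pmax(pmin(tdeath, 1), 1e-6)
  }
  tibble(person_id = df$person_id, entry_age = df$age,
         exit_age = pmax(exit, df$age + 1e-6),
         event = as.integer(event),
         state = df$from_state)
}

#' Fit Weibull mortality on the age time-scale
#'
#' Proportional-hazards Weibull regression of death on severity state, with
#' age as the time scale (left truncation at each record's entry age).
#' Under the 4-level scheme the reference level is Very mild; the
#' `merge_verymild` variant pools Very mild with Mild (the low-mortality
#' alternative in which one-year death probabilities are predicted directly
#' from the parametric fit rather than via hazard ratios on a life table).
#'
#' @param records Output of [survival_records()].
#' @param merge_verymild Pool Very mild with Mild before fitting.
#' @param mode `"hr_on_lifetable"` (default) or `"direct_weibull"`.
#' @return An object of class `mortality_model`: Weibull `shape` and `rate`
#'   (PH parameterization, cumulative hazard `rate * t^shape`), named
#'   `hazard_ratios` (reference level 1), `mode`, and the flexsurv fit.
#' @export
fit_weibull_mortality <- function(records,
                                  merge_verymild = FALSE,
                                  mode = c("hr_on_lifetable", "direct_weibull")) {
  mode <- match.arg(mode)
  df <- as_tibble(records)
  df$state <- droplevels(factor(df$state))
  if (merge_verymild && "VeryMild" %in% levels(df$state)) {
    levels(df$state)[levels(df$state) == "VeryMild"] <- "Mild"
  }
  ev <- tapply(df$event, df$state, sum)
  if (any(ev == 0, na.rm = TRUE)) {
    abort(sprintf("no deaths observed in stratum: %s",
                  paste(names(ev)[which(ev == 0)], collapse = ", ")),
          class = "admarkov_fit_error")
  }
  # data-driven starting values: flexsurv's defaults (from survreg) do not
  # handle left truncation on the age time-scale well
  crude <- sum(df$event) / sum(df$exit_age - df$entry_age)
  k0 <- 5
  t_bar <- mean(df$exit_age)
  inits <- c(k0, crude / (k0 * t_bar^(k0 - 1)),
             rep(0, nlevels(df$state) - 1L))
  fit <- flexsurv::flexsurvreg(
    survival::Surv(entry_age, exit_age, event) ~ state,
    data = df, dist = "weibullPH", inits = inits)
  cf <- fit$res[, "est"]
  st_terms <- grep("^state", names(cf), value = TRUE)
  hr <- c(1, exp(cf[st_terms]))
  names(hr) <- c(levels(df$state)[1L], sub("^state", "", st_terms))
  structure(list(shape = unname(cf[["shape"]]), rate = unname(cf[["scale"]]),
                 hazard_ratios = hr, mode = mode, fit = fit),
            class = "mortality_model")
}

#' Construct a mortality model directly from parameters
#'
#' @param hazard_ratios Named hazard ratios per severity state (reference
#'   states get 1).
#' @param mode `"hr_on_lifetable"` or `"direct_weibull"`.
#' @param shape,rate Weibull PH parameters (needed for `direct_weibull`).
#' @return A `mortality_model` object.
#' @export
mortality_model <- function(hazard_ratios,
                            mode = c("hr_on_lifetable", "direct_weibull"),
                            shape = NULL, rate = NULL) {
  mode <- match.arg(mode)
  if (any(hazard_ratios <= 0)) stop_param("hazard ratios must be positive")
  if (mode == "direct_weibull" && (is.null(shape) || is.null(rate))) {
    stop_param("direct_weibull mode needs `shape` and `rate`")
  }
  structure(list(shape = shape, rate = rate, hazard_ratios = hazard_ratios,
                 mode = mode, fit = NULL),
            class = "mortality_model")
}

#' One-year death probability from a life-table probability and hazard ratio
#'
#' Applies the published composition exactly as printed:
#' `1 - exp(-q * HR)`, where `q` is the age-specific annual death
#' probability and HR the severity hazard ratio. The probability itself
#' (not a converted rate) enters the exponent; the mathematically cleaner
#' rate-based alternative `1 - (1 - q)^HR` is available via
#' `method = "rate"` but is not the default.
#'
#' @param q Annual death probability in `[0, 1]`.
#' @param hr Hazard ratio, `>= 0`.
#' @param method `"probability"` (as printed; default) or `"rate"`.
#' @return One-year death probability.
#' @examples
#' death_probability(0.01, 1)  # 0.00995017
#' death_probability(0.02, 2)  # 0.039211
#' @export
death_probability <- function(q, hr, method = c("probability", "rate")) {
  method <- match.arg(method)
  check_prob(q, "q")
  if (any(hr < 0)) stop_domain("`hr` must be non-negative")
  if (method == "probability") 1 - exp(-q * hr) else 1 - (1 - q)^hr
}

#' One-year death probabilities for all model states at an age
#' @keywords internal
#' @noRd
state_death_probs <- function(mortality, life_table, age,
                              method = "probability") {
  hr <- c(MCI = 1,
          Mild = unname(mortality$hazard_ratios["Mild"]),
          Moderate = unname(mortality$hazard_ratios["Moderate"]),
          Severe = unname(mortality$hazard_ratios["Severe"]))
  if (mortality$mode == "direct_weibull") {
    h0 <- mortality$rate * ((age + 1)^mortality$shape - age^mortality$shape)
    p <- 1 - exp(-h0 * hr)
    p["MCI"] <- lookup_q(life_table, age)  # MCI mortality = general population
    pmin(pmax(p, 0), 1)
  } else {
    q <- lookup_q(life_table, age)
    death_probability(q, hr, method = method)
  }
}

#' Fit the gamma cost regression
#'
#' Log-link gamma GLM of annual societal cost on age and severity state.
#'
#' @param records Tibble with columns `age`, `state`, `annual_cost` (> 0).
#' @return An object of class `cost_model` wrapping the glm fit.
#' @export
fit_cost_glm <- function(records) {
  df <- as_tibble(records)
  if (any(df$annual_cost <= 0)) stop_domain("annual costs must be positive")
  fit <- glm(annual_cost ~ age + state, family = Gamma(link = "log"), data = df)
  structure(list(fit = fit, coefficients = coef(fit),
                 dispersion = summary(fit)$dispersion,
                 levels = levels(factor(df$state))),
            class = "cost_model")
}

#' Predicted annual cost
#'
#' @param model A [fit_cost_glm()] object.
#' @param age Age in years.
#' @param state Severity state.
#' @return Predicted annual cost (SEK/year), `exp` of the linear predictor.
#' @export
predict_cost <- function(model, age, state) {
  stopifnot(inherits(model, "cost_model"))
  nd <- data.frame(age = age, state = factor(state, levels = model$levels))
  unname(predict(model$fit, newdata = nd, type = "response"))
}

#' Age-linear utility model with per-state decrements
#'
#' Baseline utility is `slope * (age - age_offset) + intercept`; each state
#' subtracts its decrement. The same age slope applies in every state, and
#' values are bounded to the EQ-5D-3L value-set range `[-0.594, 1]`.
#' The Death state has utility 0.
#'
#' @param slope Utility change per year of age (default -0.002464).
#' @param intercept Utility at `age_offset` years (default 0.962679).
#' @param decrements Named non-negative decrements per living state,
#'   non-decreasing with severity (MCI default 0).
#' @param age_offset Age at which the intercept applies (0 = raw age enters
#'   the formula, the default; 25 reproduces the alternative reading in
#'   which the regression is anchored at its youngest observed ages).
#' @return An object of class `utility_model`.
#' @export
utility_model <- function(slope = -0.002464, intercept = 0.962679,
                          decrements = c(MCI = 0, Mild = 0.16,
                                         Moderate = 0.35, Severe = 0.48),
                          age_offset = 0) {
  if (any(decrements < 0)) stop_param("decrements must be non-negative")
  dm <- decrements[intersect(c("MCI", "Mild", "Moderate", "Severe"),
                             names(decrements))]
  if (is.unsorted(dm)) {
    stop_param("decrements must be non-decreasing with severity")
  }
  structure(list(slope = slope, intercept = intercept,
                 decrements = decrements, age_offset = age_offset),
            class = "utility_model")
}

#' Utility of a state at an age
#'
#' @param age Age in years (0-110).
#' @param state Severity state (`"Death"` returns 0).
#' @param model A [utility_model()].
#' @return Utility value in `[-0.594, 1]`.
#' @examples
#' m <- utility_model(decrements = c(MCI = 0))
#' utility_value(60, "MCI", m)  # -0.002464*60 + 0.962679 = 0.814839
#' @export
utility_value <- function(age, state, model) {
  stopifnot(inherits(model, "utility_model"))
  if (any(age < 0 | age > 110)) stop_domain("age must be in [0, 110]")
  base <- model$slope * (age - model$age_offset) + model$intercept
  dec <- ifelse(state == "Death", NA_real_, model$decrements[state])
  u <- ifelse(state == "Death", 0, base - dec)
  pmin(pmax(u, -0.594), 1)
}
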