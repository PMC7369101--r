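#' Parameters for the synthetic dementia-registry generator
#'
#' Bundles every quantity the generator needs to emulate a national
#' dementia quality registry: annual clinic visits with MMSE, severity
#' transitions with an exactly probit-shaped one-year law, mortality layered
#' on a general-population life table through severity hazard ratios,
#' severity-dependent informative drop-out, gamma-distributed annual costs
#' and age-linear utilities. The returned object is also the ground truth
#' that parameter-recovery tests compare estimates against.
#'
#' @param n_individuals Number of persons to simulate.
#' @param baseline_age Named numeric `(mean, sd, min, max)` in years for the
#'   age at the baseline (diagnosis) visit.
#' @param baseline_state_probs Probabilities of the baseline severity state
#'   (3-level scheme: Mild, Moderate, Severe); must sum to 1.
#' @param visit_interval Named numeric `(months, jitter_sd)`; follow-up visits
#'   are scheduled every `months` months with Gaussian jitter (sd in months).
#' @param follow_years Maximum scheduled follow-up, years.
#' @param probit_thresholds Strictly increasing cut-points of the latent
#'   one-year transition scale (one fewer than the number of severity levels).
#' @param probit_alpha Named shifts of the latent scale per previous state
#'   (reference level 0 for the best state); higher means worse next state.
#' @param age75_effect Latent shift added when age at the transition origin
#'   is >= 75 years.
#' @param life_table A life table from [generate_life_table()] (columns
#'   `age`, `q`).
#' @param hazard_ratios Named mortality hazard ratios per severity state
#'   relative to the general population; must be >= 1 and non-decreasing with
#'   severity.
#' @param dropout Named numeric `(intercept, severity)`: per-scheduled-visit
#'   drop-out on the logit scale, `severity` multiplying the 0-based severity
#'   index. Positive `severity` makes sicker patients drop out more —
#'   the informative censoring that IPCW must correct.
#' @param cost_mean Named mean annual societal cost (SEK/year) per model state
#'   (MCI and the dementia states).
#' @param cost_shape Gamma shape of annual costs (scale = mean/shape).
#' @param cost_age_coef Log-linear age effect on cost means, per year of age
#'   (0 = costs flat in age), centred at age 77.
#' @param utility Named numeric `(slope, intercept)` of the age-linear
#'   utility: `slope * age + intercept`.
#' @param corrupt `NULL`, or a named list of defect counts to inject
#'   (`short_interval`, `duplicate_date`, `after_death`, `missing_mmse`);
#'   injected defects are labelled so cleaning counts are verifiable.
#' @return A list of class `generator_params`.
#' @seealso [generate_registry()], [ground_truth()]
#' @export
generator_params <- function(n_individuals = 1000,
                             baseline_age = c(mean = 80, sd = 7, min = 60, max = 95),
                             baseline_state_probs = c(Mild = 0.55, Moderate = 0.35, Severe = 0.10),
                             visit_interval = c(months = 12, jitter_sd = 1),
                             follow_years = 8,
                             probit_thresholds = c(0.8, 2.9),
                             probit_alpha = c(Mild = 0, Moderate = 1.9, Severe = 4.2),
                             age75_effect = 0.15,
                             life_table = generate_life_table(0.007, 1.085, max_age = 100),
                             hazard_ratios = c(Mild = 1.5, Moderate = 2.2, Severe = 3.0),
                             dropout = c(intercept = -2.2, severity = 0.5),
                             cost_mean = c(MCI = 190000, Mild = 260000,
                                           Moderate = 390000, Severe = 530000),
                             cost_shape = 4,
                             cost_age_coef = 0,
                             utility = c(slope = -0.002464, intercept = 0.962679),
                             corrupt = NULL) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1 ||
      is.na(n_individuals) || n_individuals < 0) {
    stop_param("`n_individuals` must be a single non-negative count")
  }
  if (is.unsorted(probit_thresholds, strictly = TRUE)) {
    stop_param("`probit_thresholds` must be strictly increasing")
  }
  if (length(probit_thresholds) != length(probit_alpha) - 1) {
    stop_param("need one fewer threshold than severity levels")
  }
  if (abs(sum(baseline_state_probs) - 1) > 1e-8 || any(baseline_state_probs < 0)) {
    stop_param("`baseline_state_probs` must be non-negative and sum to 1")
  }
  if (any(hazard_ratios < 1) || is.unsorted(hazard_ratios)) {
    stop_param("hazard ratios must be >= 1 and ordered Mild <= Moderate <= Severe")
  }
  if (any(cost_mean <= 0) || cost_shape <= 0) {
    stop_param("cost means and shape must be positive")
  }
  validate_life_table(life_table)
  if (!is.null(corrupt)) {
    ok <- c("short_interval", "duplicate_date", "after_death", "missing_mmse")
    if (!all(names(corrupt) %in% ok)) {
      stop_param("unknown corruption class; valid: %s", paste(ok, collapse = ", "))
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    baseline_age = baseline_age, baseline_state_probs = baseline_state_probs,
    visit_interval = visit_interval, follow_years = follow_years,
    probit_thresholds = probit_thresholds, probit_alpha = probit_alpha,
    age75_effect = age75_effect, life_table = life_table,
    hazard_ratios = hazard_ratios, dropout = dropout,
    cost_mean = cost_mean, cost_shape = cost_shape,
    cost_age_coef = cost_age_coef, utility = utility, corrupt = corrupt
  ), class = "generator_params")
}

#' Build a general-population life table
#'
#' Annual death probabilities `q(age) = min(1, base_rate * growth^(age - 60))`
#' for ages 60 to `max_age`; the terminal entry is forced to 1 so the table is
#' a proper life table.
#'
#' @param base_rate Annual death probability at age 60, in (0, 1).
#' @param growth Per-year multiplicative growth of q; must be >= 1.
#' @param max_age Terminal age of the table.
#' @return A tibble with columns `age` and `q`.
#' @examples
#' generate_life_table(0.01, 1.1, max_age = 100)
#' @export
generate_life_table <- function(base_rate, growth, max_age = 100) {
  check_prob(base_rate, "base_rate", open = TRUE)
  if (growth < 1) stop_param("`growth` must be >= 1")
  age <- 60:max_age
  q <- pmin(1, base_rate * growth^(age - 60))
  q[length(q)] <- 1
  tibble(age = as.integer(age), q = q)
}

validate_life_table <- function(lt) {
  if (!all(c("age", "q") %in% names(lt))) stop_param("life table needs columns `age`, `q`")
  check_prob(lt$q, "life table q")
  ge60 <- lt$age >= 60
  if (is.unsorted(lt$q[ge60])) stop_param("life-table q must be non-decreasing from age 60")
  invisible(lt)
}

#' Look up annual death probability from a life table
#' @keywords internal
#' @noRd
lookup_q <- function(life_table, age) {
  age <- pmin(pmax(floor(age), min(life_table$age)), max(life_table$age))
  life_table$q[match(age, life_table$age)]
}

mmse_band <- function(state) {
  switch(state,
         VeryMild = 27:30, Mild = 21:30, Moderate = 10:20, Severe = 0:9)
}

#' Ground-truth parameters of a generator configuration
#'
#' Returns the exact probit thresholds and coefficients, mortality hazard
#' ratios, cost means and utility slope/intercept that
#' [generate_registry()] uses, enabling parameter-recovery tests of the
#' estimation stack.
#'
#' @param params A [generator_params()] object.
#' @return A named list with elements `probit_thresholds`, `probit_alpha`,
#'   `age75_effect`, `hazard_ratios`, `cost_mean`, `cost_shape`,
#'   `cost_age_coef`, `utility`, `dropout`, plus the implied one-year
#'   transition matrices `transition_matrix` (a function of `age75`).
#' @export
ground_truth <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  tm <- function(age75 = FALSE) {
    lev <- names(params$probit_alpha)
    thr <- params$probit_thresholds
    shift <- params$probit_alpha + if (age75) params$age75_effect else 0
    p <- t(vapply(shift, function(a) {
      cum <- pnorm(c(thr, Inf) - a)
      diff(c(0, cum))
    }, numeric(length(lev))))
    dimnames(p) <- list(from = lev, to = lev)
    p
  }
  list(probit_thresholds = params$probit_thresholds,
       probit_alpha = params$probit_alpha,
       age75_effect = params$age75_effect,
       hazard_ratios = params$hazard_ratios,
       cost_mean = params$cost_mean, cost_shape = params$cost_shape,
       cost_age_coef = params$cost_age_coef,
       utility = params$utility, dropout = params$dropout,
       transition_matrix = tm)
}

#' Generate a synthetic longitudinal dementia registry
#'
#' Simulates, per person: a baseline visit at diagnosis, a latent severity
#' path whose one-year transitions follow an ordered-probit law (previous
#' state shifts plus an age>=75 shift, standard normal noise cut at fixed
#' thresholds), integer MMSE drawn within the current state's band, mortality
#' layered on the life table as `1 - exp(-q(age) * HR_state)`, and per-visit
#' informative drop-out logistic in current severity. Optionally injects
#' labelled data defects so cleaning counts can be verified by construction.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed; identical seed and params give a byte-identical
#'   table.
#' @return A tibble (class `registry_table`) with columns `person_id`,
#'   `visit_date`, `visit_type` (baseline/followup), `age_at_visit`, `mmse`,
#'   `death_date` (`NA` if alive at end of simulation). Injected defect
#'   counts, if any, are in `attr(, "injected")`.
#' @export
generate_registry <- function(params, seed = 1) {
  stopifnot(inherits(params, "generator_params"))
  empty <- tibble(person_id = integer(), visit_date = as.Date(character()),
                  visit_type = character(), age_at_visit = numeric(),
                  mmse = integer(), death_date = as.Date(character()))
  n <- params$n_individuals
  if (n == 0) return(structure(empty, class = c("registry_table", class(empty))))
  set.seed(seed)

  lev <- names(params$probit_alpha)
  nlev <- length(lev)
  ba <- params$baseline_age
  age0 <- pmin(pmax(rnorm(n, ba[["mean"]], ba[["sd"]]), ba[["min"]]), ba[["max"]])
  base_date <- as.Date("2012-01-01") + sample.int(1461, n, replace = TRUE) - 1L
  state0 <- sample.int(nlev, n, replace = TRUE, prob = params$baseline_state_probs)

  ny <- params$follow_years + 1L          # simulate one extra year for deaths
  state <- matrix(NA_integer_, n, ny + 1L)
  state[, 1L] <- state0
  death_time <- rep(NA_real_, n)          # years since baseline
  alive <- rep(TRUE, n)
  for (y in seq_len(ny)) {
    cur <- state[, y]
    age_y <- age0 + (y - 1)
    q <- lookup_q(params$life_table, age_y)
    p_death <- 1 - exp(-q * params$hazard_ratios[cur])
    dies <- alive & (runif(n) < p_death)
    death_time[dies] <- (y - 1) + runif(sum(dies))
    alive <- alive & !dies
    latent <- params$probit_alpha[cur] + params$age75_effect * (age_y >= 75) + rnorm(n)
    nxt <- 1L + as.integer(rowSums(outer(latent, params$probit_thresholds, `>`)))
    state[, y + 1L] <- ifelse(alive, nxt, cur)
  }
  # integer MMSE within the band of the year's state
  mmse_year <- matrix(NA_integer_, n, ny + 1L)
  for (k in seq_len(nlev)) {
    idx <- which(state == k)
    band <- mmse_band(lev[k])
    mmse_year[idx] <- band[1L] + as.integer(
      floor(runif(length(idx)) * length(band)))
  }

  interval_yr <- params$visit_interval[["months"]] / 12
  jitter_yr <- params$visit_interval[["jitter_sd"]] / 12
  n_sched <- floor(params$follow_years / interval_yr)
  drop_int <- params$dropout[["intercept"]]
  drop_sev <- params$dropout[["severity"]]

  # drop-out is decided at the previous attended visit: the severity last
  # seen in clinic drives the chance of never returning (censoring is then
  # MAR given the observed history, the mechanism IPCW corrects)
  times_by_person <- vector("list", n)
  for (i in seq_len(n)) {
    times <- 0
    if (n_sched > 0) {
      sched <- seq_len(n_sched) * interval_yr + rnorm(n_sched, 0, jitter_yr)
      sched <- sched[sched > 0.1]
      last_seen <- 1L                   # year index of last attended visit
      for (tv in sched) {
        p_drop <- plogis(drop_int + drop_sev * (state[i, last_seen] - 1L))
        if (runif(1) < p_drop) break
        if (!is.na(death_time[i]) && tv >= death_time[i]) break
        times <- c(times, tv)
        last_seen <- min(max(1L, as.integer(round_half_up(tv)) + 1L), ny + 1L)
      }
    }
    times_by_person[[i]] <- times
  }
  vt <- unlist(times_by_person)
  pid <- rep.int(seq_len(n), lengths(times_by_person))
  yidx <- pmin(as.integer(round_half_up(vt)) + 1L, ny + 1L)
  out <- tibble(
    person_id = as.integer(pid),
    visit_date = base_date[pid] + as.integer(round(vt * 365.25)),
    visit_type = ifelse(vt == 0, "baseline", "followup"),
    age_at_visit = age0[pid] + vt,
    mmse = as.integer(mmse_year[cbind(pid, yidx)]),
    death_date = as.Date(ifelse(
      is.na(death_time[pid]), NA,
      base_date[pid] + round(death_time[pid] * 365.25)
    ), origin = "1970-01-01")
  )

  injected <- NULL
  if (!is.null(params$corrupt)) {
    corrupted <- inject_defects(out, params$corrupt)
    out <- corrupted$table
    injected <- corrupted$injected
  }
  out <- structure(as_tibble(out), class = c("registry_table", class(out)))
  attr(out, "injected") <- injected
  out
}

# Injects labelled defects; uses disjoint person sets per class so every
# excluded row is uniquely attributable to one cleaning rule.
inject_defects <- function(tab, corrupt) {
  counts <- lapply(corrupt, function(x) as.integer(x))
  by_person <- split(seq_len(nrow(tab)), tab$person_id)
  nvisits <- vapply(by_person, length, integer(1))
  has_death <- tapply(!is.na(tab$death_date), tab$person_id, any)
  pool <- as.integer(names(by_person))
  pick <- function(eligible, k, used) {
    cand <- setdiff(eligible, used)
    if (length(cand) < k) stop_param("not enough persons to inject defects")
    cand[seq_len(k)]
  }
  used <- integer(0)
  injected <- list()
  extra <- list()

  k <- counts$duplicate_date %||% 0L
  if (k > 0) {
    ids <- pick(pool[nvisits >= 2], k, used); used <- c(used, ids)
    for (id in ids) {
      r <- tab[by_person[[as.character(id)]][2L], ]
      extra[[length(extra) + 1L]] <- r
    }
    injected$duplicate_date <- k
  }
  k <- counts$short_interval %||% 0L
  if (k > 0) {
    ids <- pick(pool, k, used); used <- c(used, ids)
    for (id in ids) {
      r <- tab[by_person[[as.character(id)]][1L], ]
      r$visit_date <- r$visit_date + 60L
      r$visit_type <- "followup"
      r$age_at_visit <- r$age_at_visit + 60 / 365.25
      extra[[length(extra) + 1L]] <- r
    }
    injected$short_interval <- k
  }
  k <- counts$after_death %||% 0L
  if (k > 0) {
    ids <- pick(pool[as.logical(has_death)], k, used); used <- c(used, ids)
    for (id in ids) {
      r <- tab[by_person[[as.character(id)]][1L], ]
      r$visit_date <- r$death_date + 30L
      r$visit_type <- "followup"
      extra[[length(extra) + 1L]] <- r
    }
    injected$after_death <- k
  }
  k <- counts$missing_mmse %||% 0L
  if (k > 0) {
    ids <- pick(pool, k, used); used <- c(used, ids)
    tab$mmse[tab$person_id %in% ids] <- NA_integer_
    injected$missing_mmse <- k
    injected$missing_mmse_rows <- sum(tab$person_id %in% ids)
  }
  if (length(extra)) {
    tab <- bind_rows(tab, list_rbind(extra)) |>
      arrange(.data$person_id, .data$visit_date)
  }
  list(table = tab, injected = injected)
}

#' Generate annual cost records with known gamma structure
#'
#' Draws `(age, state, annual cost)` records: cost ~ Gamma with
#' `mean = cost_mean[state] * exp(cost_age_coef * (age - 77))` and the
#' configured shape. Used to test the gamma cost GLM.
#'
#' @param n Number of records.
#' @param params A [generator_params()] object.
#' @param seed Integer seed.
#' @return A tibble with columns `age`, `state`, `annual_cost`.
#' @export
generate_cost_records <- function(n, params, seed = 1) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(seed)
  states <- names(params$cost_mean)
  st <- sample(states, n, replace = TRUE)
  age <- runif(n, 60, 95)
  mu <- params$cost_mean[st] * exp(params$cost_age_coef * (age - 77))
  cost <- rgamma(n, shape = params$cost_shape, scale = mu / params$cost_shape)
  tibble(age = age, state = factor(st, levels = states), annual_cost = cost)
}
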