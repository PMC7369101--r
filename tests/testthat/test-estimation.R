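test_that("death probability composition matches the printed formula", {
  expect_equal(death_probability(0.01, 1), 1 - exp(-0.01), tolerance = 1e-12)
  expect_equal(death_probability(0.01, 1), 0.00995017, tolerance = 1e-6)
  expect_equal(death_probability(0.02, 2), 0.039211, tolerance = 1e-4)
  expect_equal(death_probability(0.5, 0), 0)
  # rate-based alternative behind the flag
  expect_equal(death_probability(0.02, 2, method = "rate"), 1 - 0.98^2,
               tolerance = 1e-12)
  expect_error(death_probability(-0.1, 1), class = "admarkov_domain_error")
  expect_error(death_probability(0.1, -1), class = "admarkov_domain_error")
})

test_that("death probability is monotone in both arguments", {
  q <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(death_probability(q, 2)) > 0))
  hr <- seq(0.5, 5, by = 0.1)
  expect_true(all(diff(death_probability(0.05, hr)) > 0))
})

test_that("utility model evaluates the age-linear formula with decrements", {
  m <- utility_model()
  expect_equal(utility_value(0, "MCI", m), 0.962679, tolerance = 1e-12)
  expect_equal(utility_value(60, "MCI", m), -0.002464 * 60 + 0.962679,
               tolerance = 1e-12)
  expect_equal(utility_value(60, "MCI", m), 0.814839, tolerance = 1e-7)
  # severity ordering at fixed age
  u <- utility_value(75, c("MCI", "Mild", "Moderate", "Severe"), m)
  expect_true(all(diff(u) < 0))
  expect_equal(utility_value(75, "Death", m), 0)
  expect_true(all(utility_value(c(0, 110), "Severe", m) >= -0.594))
  expect_error(utility_value(120, "MCI", m), class = "admarkov_domain_error")
  expect_error(utility_model(decrements = c(MCI = 0, Mild = 0.4,
                                            Moderate = 0.2, Severe = 0.5)),
               class = "admarkov_parameter_error")
  # age-25 anchored alternative shifts the intercept, not the slope
  m25 <- utility_model(age_offset = 25)
  expect_equal(utility_value(85, "MCI", m25) - utility_value(60, "MCI", m25),
               -0.002464 * 25, tolerance = 1e-12)
})

test_that("with no censoring all continuation probabilities and weights are 1", {
  tr <- tibble::tibble(person_id = rep(1:20, each = 3),
                       grid_year = rep(0:2, 20),
                       age = 70,
                       from_state = factor("Mild", levels = c("Mild", "Moderate", "Severe")),
                       to_state = factor("Mild", levels = c("Mild", "Moderate", "Severe", "Death")),
                       weight = 1)
  cm <- fit_censoring_model(tr)
  expect_equal(predict(cm, tr), rep(1, nrow(tr)))
  w <- ipcw_weights(tr, cm, stabilize = FALSE, truncate = NULL)
  expect_equal(w$weight, rep(1, nrow(tr)))
})

test_that("weights equal the inverse cumulative continuation product", {
  lev <- c("Mild", "Moderate", "Severe")
  # 80% continuation in every cell of a two-state table
  fitdat <- tibble::tibble(
    person_id = 1:200, grid_year = 0L, age = 70,
    from_state = factor(rep(c("Mild", "Moderate"), each = 100), levels = lev),
    to_state = factor(ifelse(rep(rep(c(TRUE, FALSE), c(80, 20)), 2),
                             "Mild", NA), levels = c(lev, "Death")),
    weight = 1)
  cm <- fit_censoring_model(fitdat, use_age = FALSE)
  one <- tibble::tibble(person_id = 1L, grid_year = 0:2, age = 70,
                        from_state = factor("Mild", levels = lev),
                        to_state = factor("Mild", levels = c(lev, "Death")),
                        weight = 1)
  w <- ipcw_weights(one, cm, stabilize = FALSE, truncate = NULL)
  expect_equal(w$weight, 0.8^-(1:3), tolerance = 1e-6)
  # stabilized weights scale by the fitting population's marginal
  # continuation (0.8 here), cancelling the constant hazard exactly
  ws <- ipcw_weights(one, cm, stabilize = TRUE, truncate = NULL)
  expect_equal(ws$weight, rep(1, 3), tolerance = 1e-6)
})

test_that("censoring model reproduces the analytic 2x2 logistic solution", {
  lev <- c("Mild", "Severe")
  n_m <- c(cont = 90, cens = 30)
  n_s <- c(cont = 40, cens = 40)
  mk <- function(state, cont, cens) {
    tibble::tibble(person_id = seq_len(cont + cens), grid_year = 0L, age = 70,
                   from_state = factor(state, levels = lev),
                   to_state = factor(c(rep("Mild", cont), rep(NA, cens)),
                                     levels = c(lev, "Death")),
                   weight = 1)
  }
  dat <- dplyr::bind_rows(mk("Mild", 90, 30), mk("Severe", 40, 40))
  cm <- fit_censoring_model(dat, use_age = FALSE)
  co <- coef(cm$fit)
  expect_equal(unname(co[1]), log(90 / 30), tolerance = 1e-6)
  expect_equal(unname(co[2]), log(40 / 40) - log(90 / 30), tolerance = 1e-6)
})

test_that("estimated drop-out severity effect has the generator's sign", {
  reg <- generate_registry(dropout_gen_params(2000), seed = 1)
  tr <- build_transitions(annualize_registry(clean_registry(reg)$table),
                          scheme = "3level")
  cm <- fit_censoring_model(tr)
  co <- coef(cm$fit)
  # positive drop-out coefficient on severity => lower continuation odds
  expect_lt(co[["from_stateModerate"]], 0)
  expect_lt(co[["from_stateSevere"]], co[["from_stateModerate"]])
})

test_that("ordered probit recovers a strongly diagonal transition law", {
  set.seed(42)
  lev <- c("Mild", "Moderate", "Severe")
  alpha <- c(Mild = 0, Moderate = 3, Severe = 6)
  thr <- c(1.5, 4.5)
  n <- 900
  from <- sample(lev, n, replace = TRUE)
  latent <- alpha[from] + rnorm(n)
  to <- lev[1 + rowSums(outer(latent, thr, `>`))]
  tr <- tibble::tibble(person_id = seq_len(n), grid_year = 0L,
                       age = 70,
                       from_state = factor(from, levels = lev),
                       to_state = factor(to, levels = c(lev, "Death")),
                       weight = 1)
  fit <- fit_ordered_probit(tr, use_age75 = FALSE)
  m <- transition_matrix(fit)
  expect_equal(rowSums(m), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(diag(m) > 0.85))
  # cut-points recovered within 3 standard errors
  se <- sqrt(diag(vcov(fit$fit)))
  z1 <- (fit$cutpoints[[1]] - thr[1]) / se[["Mild|Moderate"]]
  z2 <- (fit$cutpoints[[2]] - thr[2]) / se[["Moderate|Severe"]]
  expect_lt(max(abs(c(z1, z2))), 3)
})

test_that("predicted transition matrices are row-stochastic for both age groups", {
  reg <- generate_registry(clean_gen_params(1500), seed = 3)
  tr <- build_transitions(annualize_registry(clean_registry(reg)$table),
                          scheme = "3level")
  fit <- fit_ordered_probit(tr)
  for (a in c(FALSE, TRUE)) {
    m <- transition_matrix(fit, age75 = a)
    expect_equal(rowSums(m), rep(1, nrow(m)), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_true(all(m >= 0))
  }
})

test_that("Weibull fit recovers the exponential special case with known ratios", {
  set.seed(7)
  n <- 4000
  state <- factor(sample(c("Mild", "Severe"), n, replace = TRUE),
                  levels = c("Mild", "Severe"))
  rate <- ifelse(state == "Mild", 0.05, 0.15)
  t_death <- rexp(n, rate)
  cens_t <- 30
  rec <- tibble::tibble(person_id = seq_len(n),
                        entry_age = 1e-3,
                        exit_age = pmin(t_death, cens_t) + 1e-3,
                        event = as.integer(t_death <= cens_t),
                        state = state)
  mm <- fit_weibull_mortality(rec)
  expect_equal(mm$shape, 1, tolerance = 0.1)
  lse <- mm$fit$res[grep("Severe", rownames(mm$fit$res)), "se"]
  expect_lt(abs(log(mm$hazard_ratios[["Severe"]]) - log(3)), 3 * lse)
})

test_that("identical hazards across states give ratios near one", {
  set.seed(8)
  n <- 3000
  state <- factor(sample(c("Mild", "Moderate", "Severe"), n, replace = TRUE))
  t_death <- rexp(n, 0.1)
  rec <- tibble::tibble(person_id = seq_len(n), entry_age = 1e-3,
                        exit_age = pmin(t_death, 25) + 1e-3,
                        event = as.integer(t_death <= 25), state = state)
  mm <- fit_weibull_mortality(rec)
  expect_true(all(abs(log(mm$hazard_ratios)) < 0.15))
})

test_that("mortality fit fails informatively when a stratum has no events", {
  rec <- tibble::tibble(person_id = 1:40, entry_age = 60,
                        exit_age = 61,
                        event = rep(c(1L, 0L), each = 20),
                        state = factor(rep(c("Mild", "Severe"), each = 20)))
  expect_error(fit_weibull_mortality(rec), regexp = "Severe",
               class = "admarkov_fit_error")
})

test_that("gamma cost GLM recovers generator effects and calibrates to the mean", {
  p <- generator_params(cost_mean = c(MCI = 100000, Mild = 200000,
                                      Moderate = 300000, Severe = 400000),
                        cost_age_coef = 0)
  rec <- generate_cost_records(5000, p, seed = 1)
  cm <- fit_cost_glm(rec)
  co <- summary(cm$fit)$coefficients
  # state effect Severe vs MCI: truth log(4)
  z <- (co["stateSevere", "Estimate"] - log(4)) / co["stateSevere", "Std. Error"]
  expect_lt(abs(z), 3)
  # zero generating age coefficient: predictions flat in age
  z_age <- co["age", "Estimate"] / co["age", "Std. Error"]
  expect_lt(abs(z_age), 3)
  pr <- predict_cost(cm, c(65, 90), c("Mild", "Mild"))
  expect_lt(abs(pr[2] / pr[1] - 1), 0.1)
  # fitted means track observed means per state
  for (s in levels(rec$state)) {
    obs <- mean(rec$annual_cost[rec$state == s])
    fitm <- mean(predict(cm$fit, type = "response")[rec$state == s])
    expect_lt(abs(fitm / obs - 1), 0.02)
  }
  expect_error(fit_cost_glm(dplyr::mutate(rec, annual_cost = annual_cost - 2e5)),
               class = "admarkov_domain_error")
})
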