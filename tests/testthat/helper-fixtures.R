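# Generator configurations shared across tests.

# fully observed cohort: visits exactly on anniversaries, no drop-out
clean_gen_params <- function(n, ...) {
  generator_params(n_individuals = n,
                   visit_interval = c(months = 12, jitter_sd = 0),
                   dropout = c(intercept = -30, severity = 0),
                   ...)
}

# informative drop-out driven by the severity last seen in clinic
dropout_gen_params <- function(n, ...) {
  generator_params(n_individuals = n,
                   dropout = c(intercept = -1.5, severity = 0.8),
                   ...)
}

# zero-mortality engine inputs with a fixed progression risk and inert
# dementia rows (no movement between dementia states)
zero_mortality_inputs <- function(p = annualize_risk(0.5, 3), ...) {
  dem <- matrix(c(0, 1, 0, 0,
                  0, 0, 1, 0,
                  0, 0, 0, 1), nrow = 3, byrow = TRUE)
  model_inputs(
    annual_risk = p,
    dementia_matrix = dem,
    mortality = mortality_model(c(Mild = 1, Moderate = 1, Severe = 1)),
    life_table = tibble::tibble(age = 60:100, q = 0),
    costs = c(MCI = 1, Mild = 1, Moderate = 1, Severe = 1),
    ...
  )
}

# joint (from,to) transition frequency table, optionally weighted
joint_freq <- function(transitions, w = transitions$weight) {
  obs <- transitions[!is.na(transitions$to_state), ]
  w <- w[!is.na(transitions$to_state)]
  x <- tapply(w, list(obs$from_state, obs$to_state), sum)
  x[is.na(x)] <- 0
  x / sum(x)
}
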