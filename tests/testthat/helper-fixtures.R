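# Small deterministic cohorts used across test files.

# wrap bare columns into a minimal cohort-shaped data frame
make_cohort <- function(obs_time, event, x_bm = 0L, x_conf = 0L,
                        x_risk = 0L, x_surr = 0L) {
  n <- length(obs_time)
  df <- data.frame(
    id = seq_len(n),
    x_bm = rep_len(x_bm, n), x_conf = rep_len(x_conf, n),
    x_risk = rep_len(x_risk, n), x_surr = rep_len(x_surr, n),
    obs_time = obs_time, event = as.integer(event)
  )
  class(df) <- c("cohort", "data.frame")
  df
}

# classic risk-set toy: two events, two censored
ncc_toy <- function() {
  make_cohort(obs_time = c(1, 2, 3, 1.5), event = c(1, 1, 0, 0))
}

# counter-matching toy: one event in stratum 1, controls in both strata
cm_toy <- function() {
  make_cohort(obs_time = c(1, 2, 3), event = c(1, 0, 0),
              x_surr = c(1L, 0L, 1L))
}

# 20-subject fixture with events, censoring and both surrogate strata,
# frozen from the generator so Monte-Carlo oracles have a stable target
fixture20 <- function() {
  cfg <- scenario_config(n_phase1 = 20, censor_rate = 0.3, phase2_n = 10)
  simulate_cohort(cfg, seed = 2024)
}

# small random survival datasets for estimator cross-checks
random_surv_data <- function(n = 30, p = 2) {
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  eta <- drop(X %*% rep(0.5, p))
  time <- rexp(n, rate = 0.2 * exp(eta))
  cens <- rexp(n, rate = 0.1)
  data.frame(obs_time = pmin(time, cens), event = as.integer(time < cens), X)
}

# selection frequencies over repeated draws of one design
mc_selection_freq <- function(cohort, draw_fn, n_draws) {
  counts <- numeric(nrow(cohort))
  for (i in seq_len(n_draws)) {
    counts <- counts + draw_fn()$selected
  }
  counts / n_draws
}
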