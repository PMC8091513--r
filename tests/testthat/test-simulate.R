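test_that("logistic link evaluates the closed form", {
  expect_equal(expit_link(-2, 1.7, 0), 0.11920, tolerance = 1e-4)
  expect_equal(expit_link(0, 0, 1), 0.5)
  # marginal prevalence of the rare biomarker given a 50/50 confounder
  prev <- 0.5 * expit_link(-4, 1.5, 0) + 0.5 * expit_link(-4, 1.5, 1)
  expect_equal(prev, 0.0469, tolerance = 1e-3)
})

test_that("surrogate coefficients reproduce the target accuracy", {
  for (acc in list(c(0.7, 0.7), c(0.9, 0.7), c(0.8, 0.9))) {
    cf <- surrogate_coefs(acc[1], acc[2])
    expect_equal(expit_link(cf["intercept"], cf["slope"], 1),
                 acc[1], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(1 - expit_link(cf["intercept"], cf["slope"], 0),
                 acc[2], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Weibull inversion matches the stated survival function", {
  expect_equal(inverse_weibull_time(exp(-0.1), 0, scale = 0.1, shape = 0.9), 1)
  # inverting the survival probability at t = 2 returns t = 2
  s2 <- exp(-0.1 * 2^0.9)
  expect_equal(inverse_weibull_time(s2, 0, 0.1, 0.9), 2)
  # decreasing in u, and u -> 1 collapses the time to zero
  u <- c(0.1, 0.5, 0.9, 1 - 1e-12)
  tt <- inverse_weibull_time(u, 0.3, 0.1, 0.9)
  expect_true(all(diff(tt) < 0))
  expect_lt(tt[4], 1e-10)
  expect_error(inverse_weibull_time(0, 0, 0.1, 0.9), "strictly inside")
  expect_error(inverse_weibull_time(1, 0, 0.1, 0.9), "strictly inside")
})

test_that("simulated event times follow the Weibull PH model (KS at 1%)", {
  set.seed(401)
  for (eta in c(0, log(1.5) * 2)) {
    u <- runif(10000)
    tt <- inverse_weibull_time(u, eta, 0.1, 0.9)
    ks <- ks.test(tt, function(t) 1 - exp(-0.1 * t^0.9 * exp(eta)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("cohort generation honours the configured mechanism", {
  cfg <- scenario_config(n_phase1 = 10000, censor_rate = 0)
  co <- simulate_cohort(cfg, seed = 99)
  co2 <- simulate_cohort(cfg, seed = 99)
  expect_identical(co, co2)  # determinism
  expect_true(all(co$obs_time <= cfg$tau))
  expect_true(all(co$obs_time > 0))
  expect_identical(co$event, as.integer(co$event_time < co$censor_time))
  expect_identical(co$event == 1L, co$obs_time == co$event_time)
  # no random censoring at rho = 0
  expect_equal(random_censoring_fraction(co), 0)
  # biomarker prevalence: closed form 0.2724, 3 MC SEs at n = 10000
  mc_se <- sqrt(0.2724 * (1 - 0.2724) / 10000)
  expect_lt(abs(mean(co$x_bm) - 0.2724), 3 * mc_se)
})

test_that("random censoring appears only when the rate is positive", {
  cfg <- scenario_config(n_phase1 = 5000, censor_rate = 0.4)
  co <- simulate_cohort(cfg, seed = 5)
  expect_gt(random_censoring_fraction(co), 0.3)
  expect_true(all(co$censor_time <= cfg$tau))
})

test_that("Burton replication counts match the closed form", {
  expect_identical(burton_replications(0.0046, 0.011, 0.05), 1997L)
  expect_identical(burton_replications(0.01, 0.011, 0.05), 423L)
  v <- 0.011
  expect_identical(burton_replications(qnorm(0.975) * sqrt(v), v, 0.05), 1L)
  expect_error(burton_replications(0, 0.011), "positive")
  expect_error(burton_replications(-1, 0.011), "positive")
})

test_that("cohorts round-trip through the delimited export", {
  co <- simulate_cohort(scenario_config(n_phase1 = 50, censor_rate = 0.2),
                        seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_s3_class(back, "cohort")
  expect_equal(back$obs_time, co$obs_time)
  expect_identical(back$event, co$event)
  expect_identical(back$x_surr, co$x_surr)
})

test_that("cohort schema violations are rejected with the offending column", {
  co <- as.data.frame(simulate_cohort(scenario_config(n_phase1 = 20), seed = 1))
  expect_error(as_cohort(co[setdiff(names(co), "event")]), "event")
  bad <- co
  bad$x_bm[1] <- 2L
  expect_error(as_cohort(bad), "x_bm")
})

test_that("scenario configs read from YAML and JSON, rejecting unknown keys", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_phase1: 500", "censor_rate: 0.1", "phase2_n: 100"), y)
  cfg <- read_scenario_config(y)
  expect_equal(cfg$n_phase1, 500)
  expect_equal(cfg$censor_rate, 0.1)
  expect_equal(cfg$beta_bm, log(1.5))

  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_phase1": 500, "tau": 3}', j)
  expect_equal(read_scenario_config(j)$tau, 3)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_phase_one: 500", bad)
  expect_error(read_scenario_config(bad), "unknown scenario config key")

  expect_error(scenario_config(phase2_n = 3000), "phase2_n")
})
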