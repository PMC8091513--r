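test_that("empirical weights reproduce phase-I stratum totals exactly", {
  co <- make_cohort(obs_time = rep(1, 2000), event = rep(c(1, 0), c(500, 1500)))
  set.seed(10)
  s <- draw_cc(co, build_strata(co), 600)
  ws <- empirical_probs(co, s)
  expect_equal(unique(ws$weight[s$selected & co$event == 1]), 5 / 3)
  # weighted totals equal stratum sizes in every stratum
  for (h in levels(s$stratum)) {
    idx <- s$selected & s$stratum == h
    expect_equal(sum(ws$weight[idx]), sum(s$stratum == h))
  }
  # SRS: every weight N/n, total weight N
  srs <- draw_srs(co, 600)
  wsrs <- empirical_probs(co, srs)
  expect_true(all(abs(wsrs$weight[srs$selected] - 2000 / 600) < 1e-12))
  expect_equal(sum(wsrs$weight), 2000)
  expect_error(empirical_probs(co, draw_ncc(co, 4000)), "risk-set")
})

test_that("Samuelsen probabilities match risk-set enumeration on the toy", {
  co <- ncc_toy()
  set.seed(11)
  s <- draw_ncc(co, n_target = 4, m = 1)
  ws <- ncc_probs(co, s)
  expect_equal(ws$inclusion_prob[c(1, 2)], c(1, 1))  # cases kept certainly
  expect_equal(ws$inclusion_prob[3], 1)      # forced control of the t=2 case
  expect_equal(ws$inclusion_prob[4], 1 / 3)  # only reachable at t=1
  # non-decreasing in observed time among non-cases
  nc <- which(co$event == 0)
  ordnc <- nc[order(co$obs_time[nc])]
  expect_true(all(diff(ws$inclusion_prob[ordnc]) >= 0))
  # single-case reduction: pi = m / (R - 1) for everyone at risk
  co1 <- make_cohort(obs_time = c(1, 2, 3, 4), event = c(1, 0, 0, 0))
  s1 <- draw_ncc(co1, n_target = 2, m = 1)
  ws1 <- ncc_probs(co1, s1)
  expect_equal(ws1$inclusion_prob[2:4], rep(1 / 3, 3))
})

test_that("counter-matching probabilities respect strata and fallback", {
  co <- cm_toy()
  set.seed(12)
  s <- draw_cm(co, "x_surr", n_target = 2, m = 1)
  ws <- suppressWarnings(cm_probs(co, s))
  expect_equal(ws$inclusion_prob[2], 1)  # only opposite-stratum candidate
  # subject 3 shares the stratum of the only case: never samplable
  expect_equal(ws$inclusion_prob[3], 0)
  expect_equal(ws$weight[3], 0)
  expect_warning(cm_probs(co, s), "unreachable")
})

test_that("NCC inclusion probabilities agree with Monte-Carlo redraws", {
  co <- fixture20()
  n_events <- sum(co$event)
  set.seed(13)
  pi_ref <- NULL
  freq <- mc_selection_freq(co, function() {
    s <- draw_ncc(co, n_target = 2 * n_events, m = 1)
    if (is.null(pi_ref)) pi_ref <<- ncc_probs(co, s)$inclusion_prob
    s
  }, 20000)
  expect_lt(max(abs(freq - pi_ref)), 0.02)
})

test_that("CM inclusion probabilities agree with Monte-Carlo redraws", {
  co <- fixture20()
  n_events <- sum(co$event)
  set.seed(14)
  pi_ref <- NULL
  freq <- suppressWarnings(mc_selection_freq(co, function() {
    s <- draw_cm(co, "x_surr", n_target = 2 * n_events, m = 1)
    if (is.null(pi_ref)) pi_ref <<- cm_probs(co, s)$inclusion_prob
    s
  }, 20000))
  expect_lt(max(abs(freq - pi_ref)), 0.02)
})

test_that("post-stratification calibrates weighted totals to cell counts", {
  cfg <- scenario_config(n_phase1 = 1000, censor_rate = 0.1, phase2_n = 300)
  co <- simulate_cohort(cfg, seed = 15)
  set.seed(16)
  s <- draw_cc(co, build_strata(co), 300)
  base <- empirical_probs(co, s)
  ps <- post_stratify(base, co, s, "x_surr")
  cells <- build_strata(co, "x_surr")
  for (h in levels(cells)) {
    idx <- s$selected & cells == h
    expect_equal(sum(ps$weight[idx]), sum(cells == h))
  }
  expect_equal(sum(ps$weight), nrow(co))  # conservation
  # post-strata identical to the design strata: weights unchanged
  s2 <- draw_cc(co, build_strata(co, "x_surr"), 300)
  base2 <- empirical_probs(co, s2)
  ps2 <- post_stratify(base2, co, s2, "x_surr")
  expect_equal(ps2$weight, base2$weight, tolerance = 1e-12)
})

test_that("design_weights dispatches on the sampling design", {
  co <- fixture20()
  big <- simulate_cohort(scenario_config(n_phase1 = 400, censor_rate = 0.2,
                                         phase2_n = 100), seed = 18)
  set.seed(17)
  expect_identical(design_weights(co, draw_phase2(co, design_spec("SRS", 10)))$method,
                   "empirical")
  expect_identical(
    design_weights(co, draw_phase2(co, design_spec("NCC", 2 * sum(co$event))))$method,
    "samuelsen_ncc")
  expect_identical(
    suppressWarnings(design_weights(co, draw_phase2(co, design_spec("CM", 10))))$method,
    "samuelsen_cm")
  ps <- design_weights(big, draw_phase2(
    big, design_spec("CC", 100, post_stratify_vars = "x_surr")))
  expect_identical(ps$method, "post_stratified")
})
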