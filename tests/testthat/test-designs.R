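test_that("strata cross the event indicator with the listed variables", {
  co <- fixture20()
  s0 <- build_strata(co)
  expect_identical(nlevels(s0), 2L)
  s1 <- build_strata(co, "x_surr")
  expect_identical(nlevels(s1), 4L)
  expect_identical(levels(s1),
                   c("event=0:x_surr=0", "event=0:x_surr=1",
                     "event=1:x_surr=0", "event=1:x_surr=1"))
  # no events: case strata exist but are empty
  co0 <- make_cohort(obs_time = 1:4, event = 0, x_surr = c(0, 1, 0, 1))
  tab <- table(build_strata(co0, "x_surr"))
  expect_identical(sum(tab > 0), 2L)
  expect_true(all(tab[c("event=1:x_surr=0", "event=1:x_surr=1")] == 0))
  expect_error(build_strata(co, "nope"), "not found")
  co$bad <- co$obs_time
  expect_error(build_strata(co, "bad"), "binary")
})

test_that("simple random sampling has constant inclusion probability n/N", {
  co <- fixture20()
  set.seed(1)
  s <- draw_srs(co, 10)
  expect_identical(s$realized_n, 10L)
  expect_true(all(s$inclusion_prob == 0.5))
  full <- draw_srs(co, 20)
  expect_true(all(full$selected))
  expect_true(all(full$inclusion_prob == 1))
  expect_error(draw_srs(co, 21), "exceeds")
})

test_that("proportional allocation uses largest-remainder rounding", {
  # exact proportionality: 500 cases / 1500 controls at n = 600
  co <- make_cohort(obs_time = rep(1, 2000), event = rep(c(1, 0), c(500, 1500)))
  set.seed(2)
  s <- draw_pps(co, build_strata(co), 600)
  expect_identical(sort(unname(s$meta$planned)), c(150L, 450L))
  expect_true(all(abs(s$inclusion_prob - 0.3) < 1e-12))
  # uneven strata {1997 controls, 3 cases}: allocations {599, 1} by remainder
  co2 <- make_cohort(obs_time = rep(1, 2000), event = rep(c(0, 1), c(1997, 3)))
  s2 <- draw_pps(co2, build_strata(co2), 600)
  expect_identical(unname(s2$meta$planned), c(599L, 1L))
  # single stratum reduces to SRS probabilities
  co3 <- make_cohort(obs_time = rep(1, 40), event = rep(0, 40))
  s3 <- draw_pps(co3, factor(rep("all", 40)), 10)
  expect_true(all(s3$inclusion_prob == 0.25))
})

test_that("case-control sampling is balanced with cap-and-reallocate", {
  # printed arithmetic: 500 cases, 1500 controls, n = 600
  co <- make_cohort(obs_time = rep(1, 2000), event = rep(c(1, 0), c(500, 1500)))
  set.seed(3)
  s <- draw_cc(co, build_strata(co), 600)
  expect_equal(unique(s$inclusion_prob[co$event == 1]), 0.6)
  expect_equal(unique(s$inclusion_prob[co$event == 0]), 0.2)
  # fewer cases than n/2: take all cases, fill with controls
  co2 <- make_cohort(obs_time = rep(1, 2000), event = rep(c(1, 0), c(200, 1800)))
  s2 <- draw_cc(co2, build_strata(co2), 600)
  expect_true(all(s2$selected[co2$event == 1]))
  expect_true(all(s2$inclusion_prob[co2$event == 1] == 1))
  expect_identical(sum(s2$selected[co2$event == 0]), 400L)
  # balanced on the surrogate with case substrata 400/100: planned 150/150
  # capped at 100, shortfall reallocated -> realized 200/100 cases
  co3 <- make_cohort(obs_time = rep(1, 2000),
                     event = rep(c(1, 0), c(500, 1500)),
                     x_surr = c(rep(c(0L, 1L), c(400, 100)), rep(0:1, 750)))
  s3 <- draw_cc(co3, build_strata(co3, "x_surr"), 600)
  taken <- table(co3$x_surr[s3$selected & co3$event == 1])
  expect_identical(unname(c(taken)), c(200L, 100L))
  expect_identical(s3$realized_n, 600L)
  # an odd target gives the extra unit to the control half
  s4 <- draw_cc(co, build_strata(co), 601)
  expect_identical(sum(s4$selected & co$event == 1), 300L)
  expect_identical(sum(s4$selected & co$event == 0), 301L)
  # degenerate cohorts are refused
  co5 <- make_cohort(obs_time = rep(1, 10), event = rep(0, 10))
  expect_error(draw_cc(co5, build_strata(co5), 4), "at least one case")
})

test_that("nested case-control draws controls from each case's risk set", {
  co <- ncc_toy()
  set.seed(4)
  for (i in 1:25) {
    s <- draw_ncc(co, n_target = 4, m = 1)
    expect_true(all(s$selected[co$event == 1]))  # all cases kept
    expect_true(s$selected[3])  # the only at-risk control for the t=2 case
    expect_lte(s$realized_n, 2 * sum(co$event))
  }
  # case subsampling when the budget is below twice the events
  co2 <- fixture20()
  set.seed(5)
  s2 <- draw_ncc(co2, n_target = 4, m = 1)
  expect_identical(length(s2$meta$sampled_cases), 2L)
  expect_equal(s2$meta$case_pi, 2 / sum(co2$event))
  expect_lte(s2$realized_n, 4L)
})

test_that("counter-matching samples the opposite stratum, with fallback", {
  co <- cm_toy()
  set.seed(6)
  s <- draw_cm(co, "x_surr", n_target = 2, m = 1)
  expect_true(s$selected[1] && s$selected[2])  # case A + its certain control B
  expect_length(s$meta$fallback_cases, 0)
  # all subjects in one stratum: every case falls back, flagged
  co2 <- make_cohort(obs_time = c(1, 2, 3), event = c(1, 0, 0), x_surr = 1L)
  s2 <- draw_cm(co2, "x_surr", n_target = 2, m = 1)
  expect_identical(s2$meta$fallback_cases, 1L)
  expect_identical(s2$realized_n, 2L)
  expect_error(draw_cm(co, "x_bad", 2), "not found")
})

test_that("selection frequencies match inclusion probabilities (MC oracle)", {
  co <- fixture20()
  n_draws <- 20000
  set.seed(7)
  for (spec in list(design_spec("SRS", 8),
                    design_spec("PPS", 8, strata_vars = "x_surr"),
                    design_spec("CC", 8, strata_vars = "x_surr"))) {
    pi_ref <- NULL
    freq <- mc_selection_freq(co, function() {
      s <- draw_phase2(co, spec)
      pi_ref <<- s$inclusion_prob
      s
    }, n_draws)
    expect_lt(max(abs(freq - pi_ref)), 0.02)
  }
})

test_that("stratified draws never exceed stratum capacity", {
  co <- fixture20()
  set.seed(8)
  for (i in 1:50) {
    s <- draw_cc(co, build_strata(co, "x_surr"), 10)
    tab_sel <- table(s$stratum[s$selected])
    tab_all <- table(s$stratum)
    expect_true(all(tab_sel <= tab_all[names(tab_sel)]))
  }
})
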