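#' Summarise replication records into the standard performance measures
#'
#' Given one row per replication of a (scenario, design) cell, computes:
#' bias (mean estimate minus truth), empirical SE (sample SD of the
#' estimates), MSE (`bias^2 + empirical_se^2`, exactly), coverage of the
#' 95% CI, mean CI length, power (fraction of Wald rejections),
#' standardized bias (`100 * bias / empirical_se`), mean realized sample
#' size, and — when reference records are supplied — the design effect
#' `mean(V_SRS) / mean(V_design)` on the model-based (design) variances,
#' its MSE-based variant `MSE_SRS / MSE_design`, the empirical-variance
#' variant (diagnostic), and the efficiency versus the full cohort
#' `mean(V_full) / mean(V_design)`. Non-converged replications are
#' excluded and counted.
#'
#' @param records Data frame with columns `est`, `se`, `ci_lo`, `ci_hi`,
#'   `reject`, `realized_n`, `converged` (as produced by [run_scenario()]).
#' @param true_beta True log hazard ratio of the biomarker.
#' @param srs_records,full_records Optional record sets of the SRS design
#'   and the full-cohort fit from the same scenario; ratios are `NA` when
#'   absent.
#' @return One-row data frame (the performance summary).
#' @export
summarize_performance <- function(records, true_beta,
                                  srs_records = NULL, full_records = NULL) {
  ok <- records[records$converged %in% TRUE, , drop = FALSE]
  if (nrow(ok) < 2) stop("need at least two converged replications", call. = FALSE)
  est <- ok$est
  bias <- mean(est) - true_beta
  emp_se <- stats::sd(est)
  mse <- bias^2 + emp_se^2
  cover <- mean(ok$ci_lo <= true_beta & true_beta <= ok$ci_hi)
  ci_len <- mean(ok$ci_hi - ok$ci_lo)
  power <- mean(ok$reject)
  mean_v <- mean(ok$se^2)
  ref <- function(r) {
    if (is.null(r)) return(list(v = NA_real_, mse = NA_real_, empv = NA_real_))
    rok <- r[r$converged %in% TRUE, , drop = FALSE]
    b <- mean(rok$est) - true_beta
    list(v = mean(rok$se^2), mse = b^2 + stats::var(rok$est),
         empv = stats::var(rok$est))
  }
  srs <- ref(srs_records)
  full <- ref(full_records)
  data.frame(
    n_reps = nrow(records),
    n_converged = nrow(ok),
    n_excluded = nrow(records) - nrow(ok),
    mean_realized_n = mean(ok$realized_n),
    bias = bias,
    empirical_se = emp_se,
    mse = mse,
    standardized_bias = 100 * bias / emp_se,
    coverage = cover,
    ci_length = ci_len,
    power = power,
    mean_model_var = mean_v,
    design_effect = srs$v / mean_v,
    design_effect_mse = srs$mse / mse,
    design_effect_empirical = srs$empv / emp_se^2,
    efficiency_vs_full = full$v / mean_v
  )
}

#' Power as a function of the phase-II sample size
#'
#' Repeats [run_scenario()] for one design over a grid of phase-II sizes,
#' using the same root seed at every size (common random numbers: the
#' phase-I cohorts are shared across grid points, so the curve is
#' smoother than independent runs at equal B). Sizes infeasible for
#' risk-set designs are capped implicitly: the realized size never exceeds
#' twice the number of events, and the mean realized size is reported
#' alongside the power.
#'
#' @param config A [scenario_config()].
#' @param design A [design_spec()] whose `n_target` is overridden by the
#'   grid.
#' @param n_grid Integer vector of phase-II sizes.
#' @param B Replications per size.
#' @param seed Root seed.
#' @param covariates Covariates of the fitted Cox model.
#' @return Data frame with one row per size: `n`, `power`,
#'   `mean_realized_n`, `n_converged`.
#' @export
power_curve <- function(config, design, n_grid, B, seed,
                        covariates = c("x_bm", "x_conf")) {
  rows <- lapply(n_grid, function(ni) {
    d <- design
    d$n_target <- as.integer(ni)
    run <- run_scenario(config, designs = list(design = d), B = B, seed = seed,
                        covariates = covariates, fit_full = FALSE)
    rec <- run$records[run$records$design == "design", , drop = FALSE]
    ok <- rec[rec$converged %in% TRUE, , drop = FALSE]
    data.frame(n = ni, power = mean(ok$reject),
               mean_realized_n = mean(ok$realized_n),
               n_converged = nrow(ok))
  })
  do.call(rbind, rows)
}
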