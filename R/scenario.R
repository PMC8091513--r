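#' Scenario configuration for a two-phase simulation study
#'
#' Bundles every generative and design parameter of one simulation scenario:
#' the phase-I cohort size and follow-up, the Weibull baseline hazard, the
#' log hazard ratios of biomarker, confounder and risk factor, the logistic
#' links generating biomarker (given confounder) and surrogate (given
#' biomarker), the marginal covariate prevalences, the exponential random
#' censoring rate, and the phase-II sampling size and matching ratio.
#'
#' Defaults reproduce the reference scenario: a cohort of `N = 2000`
#' followed to `tau = 2` under a Weibull hazard with shape 0.9 and scale
#' 0.1, a common biomarker (marginal prevalence ~25%, `a = -2`, `b = 1.7`),
#' a surrogate with sensitivity = specificity = 0.7, a confounder with
#' prevalence 0.5, a risk factor with prevalence 0.4, hazard ratios of 1.5
#' for all three covariates, and a phase-II sample of 600 with 1:1 matching
#' for the risk-set designs.
#'
#' @param n_phase1 Phase-I cohort size (N).
#' @param tau Administrative censoring time (end of follow-up).
#' @param weibull_shape,weibull_scale Shape `p` and scale `lambda` of the
#'   baseline Weibull hazard `h0(t) = lambda * p * t^(p-1)`.
#' @param beta_bm,beta_conf,beta_risk Log hazard ratios of biomarker,
#'   confounder and risk factor.
#' @param bm_intercept,bm_slope Logistic coefficients `a`, `b` of
#'   `P(X_BM = 1 | X_Conf) = expit(a + b * X_Conf)`.
#' @param surr_intercept,surr_slope Logistic coefficients `c`, `d` of
#'   `P(X_Surr = 1 | X_BM) = expit(c + d * X_BM)`; see [surrogate_coefs()]
#'   to derive them from a target sensitivity/specificity.
#' @param p_conf,p_risk Marginal prevalences of confounder and risk factor.
#' @param censor_rate Rate `rho` of the exponential random censoring time
#'   (0 disables random censoring; administrative censoring at `tau`
#'   always applies).
#' @param phase2_n Planned phase-II sample size (n); defaults to 600 or
#'   the cohort size, whichever is smaller.
#' @param controls_per_case Matching ratio `m` for nested case-control and
#'   counter-matching designs.
#' @param seed Optional integer seed stored with the scenario.
#' @return An object of class `scenario_config` (a validated named list).
#' @examples
#' cfg <- scenario_config()
#' cfg_rare <- scenario_config(bm_intercept = -4, bm_slope = 1.5)
#' @export
scenario_config <- function(n_phase1 = 2000,
                            tau = 2,
                            weibull_shape = 0.9,
                            weibull_scale = 0.1,
                            beta_bm = log(1.5),
                            beta_conf = log(1.5),
                            beta_risk = log(1.5),
                            bm_intercept = -2,
                            bm_slope = 1.7,
                            surr_intercept = surrogate_coefs(0.7, 0.7)[["intercept"]],
                            surr_slope = surrogate_coefs(0.7, 0.7)[["slope"]],
                            p_conf = 0.5,
                            p_risk = 0.4,
                            censor_rate = 0,
                            phase2_n = min(600, n_phase1),
                            controls_per_case = 1,
                            seed = NULL) {
  cfg <- list(
    n_phase1 = n_phase1, tau = tau,
    weibull_shape = weibull_shape, weibull_scale = weibull_scale,
    beta_bm = beta_bm, beta_conf = beta_conf, beta_risk = beta_risk,
    bm_intercept = bm_intercept, bm_slope = bm_slope,
    surr_intercept = surr_intercept, surr_slope = surr_slope,
    p_conf = p_conf, p_risk = p_risk,
    censor_rate = censor_rate,
    phase2_n = phase2_n, controls_per_case = controls_per_case,
    seed = seed
  )
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(
    num1(cfg$n_phase1), cfg$n_phase1 >= 1, cfg$n_phase1 == round(cfg$n_phase1),
    num1(cfg$tau), cfg$tau > 0,
    num1(cfg$weibull_shape), cfg$weibull_shape > 0,
    num1(cfg$weibull_scale), cfg$weibull_scale > 0,
    num1(cfg$beta_bm), num1(cfg$beta_conf), num1(cfg$beta_risk),
    num1(cfg$bm_intercept), num1(cfg$bm_slope),
    num1(cfg$surr_intercept), num1(cfg$surr_slope),
    num1(cfg$p_conf), cfg$p_conf >= 0, cfg$p_conf <= 1,
    num1(cfg$p_risk), cfg$p_risk >= 0, cfg$p_risk <= 1,
    num1(cfg$censor_rate), cfg$censor_rate >= 0,
    num1(cfg$phase2_n), cfg$phase2_n >= 1, cfg$phase2_n == round(cfg$phase2_n),
    num1(cfg$controls_per_case), cfg$controls_per_case >= 1
  )
  if (cfg$phase2_n > cfg$n_phase1) {
    stop("phase2_n must not exceed n_phase1", call. = FALSE)
  }
  if (!is.null(cfg$seed)) stopifnot(num1(cfg$seed))
  invisible(cfg)
}

#' Logistic coefficients of a surrogate with given sensitivity/specificity
#'
#' The surrogate is generated as `P(X_Surr = 1 | X_BM) = expit(c + d * X_BM)`,
#' so sensitivity `P(Surr = 1 | BM = 1) = expit(c + d)` and specificity
#' `P(Surr = 0 | BM = 0) = 1 - expit(c)`. This inverts that map.
#'
#' @param sensitivity,specificity Target accuracy of the surrogate, both in
#'   (0, 1).
#' @return Named numeric vector with elements `intercept` (c) and `slope` (d).
#' @examples
#' surrogate_coefs(0.7, 0.7)
#' @export
surrogate_coefs <- function(sensitivity, specificity) {
  stopifnot(sensitivity > 0, sensitivity < 1, specificity > 0, specificity < 1)
  cc <- stats::qlogis(1 - specificity)
  d <- stats::qlogis(sensitivity) - cc
  c(intercept = cc, slope = d)
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' Keys must be named exactly as the arguments of [scenario_config()];
#' unknown keys are an error, missing keys take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: '", ext, "' (use yaml or json)",
         call. = FALSE)
  )
  if (is.null(vals) || !length(vals)) vals <- list()
  known <- setdiff(names(formals(scenario_config)), "...")
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown scenario config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, vals)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Two-phase simulation scenario\n")
  cat(sprintf("  phase I: N = %d, tau = %g, Weibull(shape %g, scale %g)\n",
              x$n_phase1, x$tau, x$weibull_shape, x$weibull_scale))
  cat(sprintf("  log HRs: BM %.4f, Conf %.4f, Risk %.4f\n",
              x$beta_bm, x$beta_conf, x$beta_risk))
  sens <- expit_link(x$surr_intercept, x$surr_slope, 1)
  spec <- 1 - expit_link(x$surr_intercept, x$surr_slope, 0)
  cat(sprintf("  biomarker link: a = %g, b = %g; surrogate sens %.2f / spec %.2f\n",
              x$bm_intercept, x$bm_slope, sens, spec))
  cat(sprintf("  P(Conf) = %g, P(Risk) = %g, censor rate = %g\n",
              x$p_conf, x$p_risk, x$censor_rate))
  cat(sprintf("  phase II: n = %d, m = %d controls/case\n",
              x$phase2_n, x$controls_per_case))
  invisible(x)
}
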