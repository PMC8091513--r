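#' Logistic (expit) link used by the covariate generators
#'
#' Evaluates `expit(intercept + slope * x)`, the conditional probability
#' behind both the biomarker-given-confounder and surrogate-given-biomarker
#' Bernoulli draws.
#'
#' @param intercept,slope Logistic coefficients.
#' @param x Covariate value(s), typically 0/1.
#' @return Probability vector, bounded in (0, 1) by construction.
#' @examples
#' expit_link(-2, 1.7, 0)   # 0.1192
#' expit_link(0, 0, 1)      # 0.5
#' @export
expit_link <- function(intercept, slope, x) {
  stats::plogis(intercept + slope * x)
}

#' Invert the Weibull proportional-hazards survival function
#'
#' Event times are generated as
#' `T = (-log(u) / (scale * exp(eta)))^(1/shape)`, so that the survival
#' function of `T` at `t` for linear predictor `eta` is
#' `exp(-scale * t^shape * exp(eta))`.
#'
#' @param u Uniform(0,1) draw(s), strictly inside the open interval.
#' @param linear_predictor Linear predictor `eta = beta'X` (vectorised).
#' @param scale,shape Weibull scale (`lambda`) and shape (`p`), both > 0.
#' @return Positive event time(s); decreasing in `u`.
#' @examples
#' inverse_weibull_time(exp(-0.1), 0, scale = 0.1, shape = 0.9)  # exactly 1
#' @export
inverse_weibull_time <- function(u, linear_predictor, scale, shape) {
  stopifnot(scale > 0, shape > 0)
  if (any(u <= 0 | u >= 1)) {
    stop("u must lie strictly inside (0, 1)", call. = FALSE)
  }
  (-log(u) / (scale * exp(linear_predictor)))^(1 / shape)
}

#' Simulate a phase-I cohort
#'
#' Draws the confounder and risk factor as independent Bernoulli variables,
#' the biomarker from its logistic link on the confounder, and the
#' surrogate from its logistic link on the biomarker. Event times come from
#' the Weibull proportional-hazards inversion with linear predictor
#' `beta_bm*X_BM + beta_conf*X_Conf + beta_risk*X_Risk`; random censoring
#' is exponential with rate `censor_rate`, truncated at `tau`
#' (administrative censoring), so `censor_time <= tau` always. The
#' observed time is `Z = min(T, C)` and the event indicator
#' `Delta = I(T < C)`.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`.
#'   Identical seeds give identical cohorts.
#' @return A `data.frame` of class `cohort` with columns `id`, `x_bm`,
#'   `x_conf`, `x_risk`, `x_surr`, `event_time`, `censor_time`,
#'   `obs_time`, `event`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_scenario_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_phase1
  x_conf <- stats::rbinom(n, 1L, config$p_conf)
  x_risk <- stats::rbinom(n, 1L, config$p_risk)
  x_bm <- stats::rbinom(n, 1L, expit_link(config$bm_intercept, config$bm_slope, x_conf))
  x_surr <- stats::rbinom(n, 1L, expit_link(config$surr_intercept, config$surr_slope, x_bm))
  eta <- config$beta_bm * x_bm + config$beta_conf * x_conf + config$beta_risk * x_risk
  u <- stats::runif(n)
  event_time <- inverse_weibull_time(u, eta, config$weibull_scale, config$weibull_shape)
  censor_time <- if (config$censor_rate > 0) {
    pmin(stats::rexp(n, config$censor_rate), config$tau)
  } else {
    rep(config$tau, n)
  }
  obs_time <- pmin(event_time, censor_time)
  event <- as.integer(event_time < censor_time)
  out <- data.frame(
    id = seq_len(n),
    x_bm = x_bm, x_conf = x_conf, x_risk = x_risk, x_surr = x_surr,
    event_time = event_time, censor_time = censor_time,
    obs_time = obs_time, event = event
  )
  class(out) <- c("cohort", "data.frame")
  attr(out, "tau") <- config$tau
  out
}

#' Number of replications for a target accuracy (Burton's formula)
#'
#' `B = ceiling((z_{1-alpha/2} * sqrt(coef_variance) / accuracy)^2)`: the
#' number of simulation replications needed so that the Monte-Carlo
#' half-width of the mean coefficient estimate is at most `accuracy`.
#'
#' @param accuracy Target half-width of the (1-alpha) interval on the mean
#'   estimate; must be positive.
#' @param coef_variance Anticipated variance of the coefficient estimate.
#' @param alpha Significance level (default 0.05).
#' @return Integer replication count. Reporting often rounds this to two
#'   significant figures (e.g. 1997 -> 2000).
#' @examples
#' burton_replications(0.0046, 0.011)  # 1997
#' @export
burton_replications <- function(accuracy, coef_variance, alpha = 0.05) {
  stopifnot(coef_variance > 0, alpha > 0, alpha < 1)
  if (!is.numeric(accuracy) || accuracy <= 0) {
    stop("accuracy must be a positive number", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling((z * sqrt(coef_variance) / accuracy)^2))
}

#' Fraction of cohort subjects randomly censored before follow-up end
#'
#' Counts subjects whose exponential censoring time fell before both their
#' event time and `tau`; purely administrative censoring at `tau` is not
#' counted, matching the convention that a scenario without random
#' censoring has a censoring rate of 0.
#'
#' @param cohort A cohort data frame.
#' @param tau End of follow-up; defaults to the `tau` attribute of the
#'   cohort or, failing that, the maximum observed time.
#' @return A proportion in \[0, 1\].
#' @export
random_censoring_fraction <- function(cohort, tau = NULL) {
  if (is.null(tau)) tau <- attr(cohort, "tau")
  if (is.null(tau)) tau <- max(cohort$obs_time)
  mean(cohort$event == 0 & cohort$obs_time < tau)
}

cohort_export_cols <- c("id", "obs_time", "event", "x_bm", "x_conf", "x_risk", "x_surr")

#' Write / read a cohort as a delimited table
#'
#' The on-disk schema is one row per subject with header
#' `id, obs_time, event, x_bm, x_conf, x_risk, x_surr` (0/1 coding, times
#' in the model's time unit), tab-separated.
#'
#' @param cohort Cohort data frame (extra columns are dropped on export).
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   validated `cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_export_cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(cohort[cohort_export_cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as_cohort(df)
}

#' Validate a user-supplied data frame as a phase-I cohort
#'
#' Checks the documented schema: `id`, positive `obs_time`, 0/1 `event`,
#' and 0/1 covariate columns `x_bm`, `x_conf`, `x_risk`, `x_surr`.
#'
#' @param df A data frame.
#' @return The data frame with class `cohort` prepended.
#' @export
as_cohort <- function(df) {
  missing_cols <- setdiff(cohort_export_cols, names(df))
  if (length(missing_cols)) {
    stop("cohort schema violation: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (v in c("event", "x_bm", "x_conf", "x_risk", "x_surr")) {
    if (!all(df[[v]] %in% c(0L, 1L))) {
      stop("cohort schema violation: column '", v, "' must be 0/1",
           call. = FALSE)
    }
  }
  if (any(df$obs_time <= 0)) {
    stop("cohort schema violation: column 'obs_time' must be positive",
         call. = FALSE)
  }
  if (!inherits(df, "cohort")) class(df) <- c("cohort", class(df))
  df
}
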