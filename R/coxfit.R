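#' Fit an inverse-probability-weighted Cox model
#'
#' Maximises the weighted Breslow partial log-likelihood
#' `l(beta) = sum_{i: event} w_i * (eta_i - log sum_{j: Z_j >= Z_i} w_j exp(eta_j))`
#' by Newton–Raphson with step-halving. Ties are handled by Breslow's
#' approximation (tied subjects share the full risk set), which makes the
#' fit exactly equivalent to row duplication for integer weights.
#' Convergence is declared when the largest absolute score component falls
#' below `1e-9` or the relative log-likelihood change does, within 50
#' iterations; non-convergence and monotone-likelihood (separation) are
#' flagged on the result, not raised.
#'
#' @param data Data frame with columns `obs_time`, `event` and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @param weights Optional per-row weights (`1/pi`); rows with weight 0 or
#'   `NA` are excluded. Default: unweighted (all 1).
#' @param init Starting coefficients (default 0).
#' @param max_iter,tol Newton–Raphson controls.
#' @return An object of class `wcox_fit` with elements `coefficients`,
#'   `var` (currently model-based, see [twophase_variance()]), `var_model`
#'   (inverse weighted information), `se`, `ci95`, `wald_p`, `loglik`,
#'   `score`, `iterations`, `converged`, `flags`, `n_used`, and the data
#'   internals needed for influence computations.
#' @examples
#' d <- data.frame(obs_time = c(1, 2, 3, 1.5), event = c(1, 1, 0, 0),
#'                 x = c(1, 0, 1, 0))
#' fit <- fit_weighted_cox(d, "x")
#' coef(fit)  # 0: the score is exactly zero at beta = 0
#' @export
fit_weighted_cox <- function(data, covariates, weights = NULL,
                             init = NULL, max_iter = 50L, tol = 1e-9) {
  stopifnot(all(c("obs_time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  n_all <- nrow(data)
  w <- if (is.null(weights)) rep(1, n_all) else weights
  stopifnot(length(w) == n_all)
  keep <- !is.na(w) & w > 0
  data <- data[keep, , drop = FALSE]
  w <- w[keep]
  n <- nrow(data)
  p <- length(covariates)
  X <- as.matrix(data[covariates])
  storage.mode(X) <- "double"
  time <- data$obs_time
  status <- data$event
  if (sum(status) < 1) stop("no events among weighted subjects", call. = FALSE)

  flags <- character(0)
  # degenerate contrast: a covariate constant among the used rows
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    flags <- c(flags, "no_contrast")
    res <- list(coefficients = stats::setNames(rep(NA_real_, p), covariates),
                var = matrix(NA_real_, p, p), var_model = matrix(NA_real_, p, p),
                se = rep(NA_real_, p), ci95 = matrix(NA_real_, p, 2),
                wald_p = rep(NA_real_, p), loglik = NA_real_,
                score = rep(NA_real_, p),
                iterations = 0L, converged = FALSE, flags = flags,
                n_used = n, covariates = covariates,
                X = X, time = time, status = status, weights = w)
    class(res) <- "wcox_fit"
    return(res)
  }

  # sort once, descending in time; risk sums become cumulative sums;
  # tied times share the cumulative sum at the end of their tie group
  ord <- order(time, decreasing = TRUE)
  Xs <- X[ord, , drop = FALSE]
  ws <- w[ord]
  ts <- time[ord]
  ds <- status[ord]
  r <- rle(ts)
  grp_end <- rep(cumsum(r$lengths), r$lengths)
  ev <- which(ds == 1)
  wev <- ws[ev]

  breslow_pieces <- function(beta) {
    eta <- drop(Xs %*% beta)
    rr <- ws * exp(eta)
    s0 <- cumsum(rr)[grp_end]
    s1 <- matrix(0, n, p)
    for (k in seq_len(p)) s1[, k] <- cumsum(rr * Xs[, k])[grp_end]
    list(eta = eta, rr = rr, s0 = s0, s1 = s1)
  }

  loglik_score_info <- function(beta) {
    pc <- breslow_pieces(beta)
    s0e <- pc$s0[ev]
    xbar <- pc$s1[ev, , drop = FALSE] / s0e
    ll <- sum(wev * (pc$eta[ev] - log(s0e)))
    U <- colSums(wev * (Xs[ev, , drop = FALSE] - xbar))
    I <- matrix(0, p, p)
    for (k in seq_len(p)) {
      for (l in k:p) {
        s2 <- cumsum(pc$rr * Xs[, k] * Xs[, l])[grp_end][ev]
        v <- sum(wev * (s2 / s0e - xbar[, k] * xbar[, l]))
        I[k, l] <- v
        I[l, k] <- v
      }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- if (is.null(init)) rep(0, p) else init
  cur <- loglik_score_info(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) {
      flags <- c(flags, "singular_information")
      break
    }
    halves <- 0L
    repeat {
      cand <- beta + step
      nxt <- loglik_score_info(cand)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      step <- step / 2
      halves <- halves + 1L
      if (halves > 20L) break
    }
    rel_change <- abs(nxt$ll - cur$ll) / (abs(cur$ll) + 1e-12)
    beta <- cand
    cur <- nxt
    if (max(abs(cur$U)) < tol || rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(beta)) > 15) {
    flags <- c(flags, "monotone_likelihood")
    converged <- FALSE
  }
  var_model <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  res <- list(
    coefficients = stats::setNames(beta, covariates),
    var = var_model, var_model = var_model,
    loglik = cur$ll, score = cur$U,
    iterations = iter, converged = converged, flags = flags,
    n_used = n, covariates = covariates,
    X = X, time = time, status = status, weights = w
  )
  class(res) <- "wcox_fit"
  refresh_inference(res)
}

# derive se / CI / Wald p from the current variance matrix
refresh_inference <- function(fit) {
  se <- sqrt(pmax(diag(fit$var), 0))
  z <- stats::qnorm(0.975)
  fit$se <- se
  fit$ci95 <- cbind(lower = fit$coefficients - z * se,
                    upper = fit$coefficients + z * se)
  fit$wald_p <- 2 * stats::pnorm(-abs(fit$coefficients / se))
  fit
}

#' @export
coef.wcox_fit <- function(object, ...) object$coefficients

#' @export
vcov.wcox_fit <- function(object, ...) object$var

#' @export
print.wcox_fit <- function(x, ...) {
  cat("Weighted Cox model (Breslow partial likelihood)\n")
  cat(sprintf("  n used = %d, iterations = %d, converged = %s\n",
              x$n_used, x$iterations, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    lower95 = x$ci95[, 1], upper95 = x$ci95[, 2],
                    p = x$wald_p)
  print(round(tab, 5))
  invisible(x)
}

# Per-subject influence (dfbeta) terms: weighted score residuals
# premultiplied by the inverse weighted information. Rows align with the
# rows used in the fit (weight > 0).
dfbeta_wcox <- function(fit) {
  X <- fit$X
  w <- fit$weights
  time <- fit$time
  status <- fit$status
  n <- nrow(X)
  p <- ncol(X)
  beta <- fit$coefficients
  ord <- order(time, decreasing = TRUE)
  Xs <- X[ord, , drop = FALSE]
  ws <- w[ord]
  ts <- time[ord]
  ds <- status[ord]
  r <- rle(ts)
  grp_end <- rep(cumsum(r$lengths), r$lengths)
  eta <- drop(Xs %*% beta)
  rr <- ws * exp(eta)
  s0 <- cumsum(rr)[grp_end]
  s1 <- matrix(0, n, p)
  for (k in seq_len(p)) s1[, k] <- cumsum(rr * Xs[, k])[grp_end]
  ev <- which(ds == 1)
  xbar_ev <- s1[ev, , drop = FALSE] / s0[ev]
  # cumulative hazard-type sums over event times t_k <= z
  et <- ts[ev]                       # descending
  aev <- ws[ev] / s0[ev]             # w_k / S0_k
  bev <- ws[ev] * s1[ev, , drop = FALSE] / s0[ev]^2
  oa <- order(et)                    # ascending event times
  et_a <- et[oa]
  cumA <- cumsum(aev[oa])
  cumB <- apply(bev[oa, , drop = FALSE], 2, cumsum)
  if (p == 1) cumB <- matrix(cumB, ncol = 1)
  idx <- findInterval(ts, et_a)      # number of event times <= Z_i
  Ai <- ifelse(idx == 0, 0, cumA[pmax(idx, 1)])
  Bi <- matrix(0, n, p)
  pos <- idx > 0
  Bi[pos, ] <- cumB[idx[pos], , drop = FALSE]
  term1 <- matrix(0, n, p)
  term1[ev, ] <- ws[ev] * (Xs[ev, , drop = FALSE] - xbar_ev)
  Us <- term1 - rr * Xs * Ai + rr * Bi
  U <- matrix(0, n, p)
  U[ord, ] <- Us  # back to original row order
  I_inv <- fit$var_model
  U %*% I_inv
}

#' Design-based variance for a weighted Cox fit
#'
#' Adds the phase-II sampling contribution to the inverse weighted
#' information (the phase-I component). For stratified designs
#' (SRS/PPS/CC, empirical or post-stratified weights) the contribution is
#' `sum_h (1 - f_h) * n_h/(n_h - 1) * sum_{i in h} (d_i - dbar_h)(d_i - dbar_h)'`
#' with `f_h = n_h / N_h` the realized sampling fraction and `d_i` the
#' per-subject influence (dfbeta) of the weighted fit. For the risk-set
#' designs (NCC/CM) a with-replacement sandwich `sum_i d_i d_i'` without
#' finite-population correction is used, shrunk per subject by
#' `(1 - pi_i)` so that a census (`pi = 1`) contributes nothing.
#'
#' @param fit A converged `wcox_fit`.
#' @param weights The `weight_set` used in the fit; `NULL` means a full
#'   (census) fit: the variance is the inverse information.
#' @param stratum_sizes Named table of phase-I stratum sizes (defaults to
#'   the cohort-level sizes recoverable from `weights$strata`).
#' @return The fit with `var`, `se`, `ci95`, `wald_p` updated; access the
#'   matrix via `vcov()`.
#' @export
twophase_variance <- function(fit, weights = NULL, stratum_sizes = NULL) {
  if (!fit$converged) {
    warning("variance requested for a non-converged fit", call. = FALSE)
  }
  if (is.null(weights)) {
    fit$var <- fit$var_model
    return(refresh_inference(fit))
  }
  d_sel <- dfbeta_wcox(fit)
  p <- ncol(d_sel)
  keep <- !is.na(weights$weight) & weights$weight > 0
  phase2 <- matrix(0, p, p)
  if (weights$method %in% c("empirical", "post_stratified")) {
    strata_sel <- droplevels(weights$strata[keep])
    if (is.null(stratum_sizes)) stratum_sizes <- table(weights$strata)
    for (h in levels(strata_sel)) {
      rows <- which(strata_sel == h)
      n_h <- length(rows)
      N_h <- as.numeric(stratum_sizes[[h]])
      if (n_h < 2) {
        warning("stratum '", h, "' has a single selected subject; ",
                "its variance contribution is dropped", call. = FALSE)
        next
      }
      f_h <- n_h / N_h
      dc <- sweep(d_sel[rows, , drop = FALSE], 2, colMeans(d_sel[rows, , drop = FALSE]))
      phase2 <- phase2 + (1 - f_h) * (n_h / (n_h - 1)) * crossprod(dc)
    }
  } else {
    pi_sel <- weights$inclusion_prob[keep]
    phase2 <- crossprod(sqrt(pmax(1 - pi_sel, 0)) * d_sel)
  }
  fit$var <- fit$var_model + phase2
  fit$var_phase2 <- phase2
  refresh_inference(fit)
}

#' Wald test of a single coefficient
#'
#' Two-sided test of `beta = 0` using the fit's current (design-based)
#' standard error.
#'
#' @param fit A `wcox_fit`.
#' @param covariate Covariate name (default: the first).
#' @param alpha Significance level (default 0.05).
#' @return List with `estimate`, `se`, `z`, `p_value`, `reject`
#'   (`NA` for a non-converged fit: no decision).
#' @export
wald_test <- function(fit, covariate = fit$covariates[1], alpha = 0.05) {
  j <- match(covariate, fit$covariates)
  if (is.na(j)) stop("unknown covariate '", covariate, "'", call. = FALSE)
  if (!fit$converged) {
    return(list(estimate = NA_real_, se = NA_real_, z = NA_real_,
                p_value = NA_real_, reject = NA))
  }
  est <- fit$coefficients[[j]]
  se <- fit$se[[j]]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  list(estimate = est, se = se, z = z, p_value = p, reject = p < alpha)
}
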