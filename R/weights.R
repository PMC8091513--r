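new_weight_set <- function(pi, selected, strata, method, extra = list()) {
  weight <- ifelse(selected & pi > 0, 1 / pi, 0)
  structure(
    c(list(inclusion_prob = pi, weight = weight, selected = selected,
           strata = strata, method = method), extra),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("Weight set (%s): %d selected, total weight %.1f\n",
              x$method, sum(x$selected), sum(x$weight)))
  if (!is.null(x$n_zero_pi) && x$n_zero_pi > 0) {
    cat(sprintf("  %d selected-population subject(s) with pi = 0 excluded\n",
                x$n_zero_pi))
  }
  invisible(x)
}

#' Empirical inclusion probabilities for stratified phase-II samples
#'
#' For SRS/PPS/CC samples the empirical inclusion probability of stratum
#' `h` is the realized number selected divided by the stratum's phase-I
#' size; weights are its reciprocal, so weighted stratum totals reproduce
#' the phase-I counts exactly.
#'
#' @param cohort Cohort data frame.
#' @param sample A `phase2_sample` from [draw_srs()], [draw_pps()] or
#'   [draw_cc()].
#' @return A `weight_set` with per-subject `inclusion_prob` and `weight`
#'   (0 for unselected subjects).
#' @export
empirical_probs <- function(cohort, sample) {
  if (sample$design %in% c("NCC", "CM")) {
    stop("use ncc_probs()/cm_probs() for risk-set designs", call. = FALSE)
  }
  strata <- sample$stratum
  sizes <- table(strata)
  picked <- table(strata[sample$selected])
  pi_h <- as.numeric(picked) / as.numeric(sizes)
  pi_h[!is.finite(pi_h)] <- 0
  if (any(pi_h == 0 & as.numeric(sizes) > 0)) {
    warning("stratum with no phase-II selections: its subjects get weight 0",
            call. = FALSE)
  }
  pi <- pi_h[as.integer(strata)]
  new_weight_set(pi, sample$selected, strata, "empirical",
                 extra = list(n_zero_pi = 0L))
}

# Cumulative Samuelsen-type escape products: given sampled-case event
# times and their per-case selection fractions m/R, returns a function
# mapping an observed time z to prod over cases with t <= z of (1 - m/R).
escape_product <- function(case_times, frac) {
  ord <- order(case_times)
  ct <- case_times[ord]
  f <- pmax(0, 1 - frac[ord])
  cp <- cumprod(f)
  function(z) {
    idx <- findInterval(z, ct)
    ifelse(idx == 0L, 1, cp[pmax(idx, 1L)])
  }
}

#' Samuelsen inclusion probabilities for a nested case-control sample
#'
#' A non-case with observed time `Z_j` belongs to the risk set of every
#' sampled case with event time `t_i <= Z_j`; at each such time the
#' probability of escaping selection is `1 - m / (R(t_i) - 1)` with
#' `R(t)` the number of subjects still at risk (`Z_k >= t`), minus one for
#' the case itself. The inclusion probability is one minus the product of
#' the escape probabilities. Cases get the design's case probability
#' (1, or the realized case sampling fraction when cases were subsampled).
#'
#' @param cohort Cohort data frame.
#' @param sample A `phase2_sample` from [draw_ncc()].
#' @param m Controls per case; defaults to the value recorded in the draw.
#' @return A `weight_set` (method `"samuelsen_ncc"`).
#' @export
ncc_probs <- function(cohort, sample, m = sample$meta$m) {
  stopifnot(sample$design == "NCC")
  n <- nrow(cohort)
  sampled_cases <- sample$meta$sampled_cases
  pi <- numeric(n)
  is_case <- cohort$event == 1
  pi[is_case] <- sample$meta$case_pi
  if (length(sampled_cases)) {
    t_case <- cohort$obs_time[sampled_cases]
    R <- vapply(t_case, function(t) sum(cohort$obs_time >= t), numeric(1))
    denom <- R - 1
    if (any(denom < m)) {
      warning("risk set(s) with fewer than m candidates: inclusion forced to 1",
              call. = FALSE)
    }
    frac <- pmin(m / pmax(denom, 1), 1)
    esc <- escape_product(t_case, frac)
    noncase <- which(!is_case)
    pi[noncase] <- 1 - esc(cohort$obs_time[noncase])
  }
  n_zero <- sum(pi == 0 & !is_case & sample$selected)
  new_weight_set(pi, sample$selected, sample$stratum, "samuelsen_ncc",
                 extra = list(n_zero_pi = as.integer(n_zero)))
}

#' Inclusion probabilities for a counter-matched sample
#'
#' The counter-matching analogue of the Samuelsen product: a non-case `j`
#' in stratum `s` can be selected at the event time of any sampled case of
#' the opposite stratum whose event time does not exceed `Z_j`, each such
#' time contributing an escape factor `1 - m / R_s(t_i)` with `R_s(t)` the
#' at-risk count within stratum `s`. Cases that had to fall back to their
#' own stratum (empty opposite risk set) contribute the corresponding
#' factor to their own stratum instead, with the case itself excluded from
#' the candidate count, so computed probabilities always match the
#' realized sampling mechanism. Subjects that no sampled case can ever
#' reach have probability 0 and are excluded from the weights (counted in
#' `n_zero_pi`, with a warning).
#'
#' @param cohort Cohort data frame.
#' @param sample A `phase2_sample` from [draw_cm()].
#' @param cm_stratum_var Binary stratum column; defaults to the draw's.
#' @param m Controls per case; defaults to the draw's.
#' @return A `weight_set` (method `"samuelsen_cm"`).
#' @export
cm_probs <- function(cohort, sample, cm_stratum_var = sample$meta$cm_stratum_var,
                     m = sample$meta$m) {
  stopifnot(sample$design == "CM")
  s <- cohort[[cm_stratum_var]]
  n <- nrow(cohort)
  sampled_cases <- sample$meta$sampled_cases
  fallback <- sample$meta$fallback_cases
  is_case <- cohort$event == 1
  pi <- numeric(n)
  pi[is_case] <- sample$meta$case_pi
  for (stratum in 0:1) {
    # cases whose control draw targets this stratum
    regular <- sampled_cases[s[sampled_cases] == 1L - stratum &
                               !(sampled_cases %in% fallback)]
    fb <- fallback[s[fallback] == stratum]
    times <- c(cohort$obs_time[regular], cohort$obs_time[fb])
    if (!length(times)) next
    at_risk <- function(t) sum(cohort$obs_time >= t & s == stratum)
    Rreg <- vapply(cohort$obs_time[regular], at_risk, numeric(1))
    Rfb <- vapply(cohort$obs_time[fb], at_risk, numeric(1)) - 1  # self excluded
    frac <- c(if (length(regular)) pmin(m / pmax(Rreg, 1), 1),
              if (length(fb)) pmin(m / pmax(Rfb, 1), 1))
    esc <- escape_product(times, frac)
    idx <- which(!is_case & s == stratum)
    pi[idx] <- 1 - esc(cohort$obs_time[idx])
  }
  n_zero <- sum(pi == 0 & !is_case)
  if (n_zero > 0) {
    warning(n_zero, " subject(s) unreachable by counter-matched sampling ",
            "(pi = 0) excluded from weights", call. = FALSE)
  }
  new_weight_set(pi, sample$selected, sample$stratum, "samuelsen_cm",
                 extra = list(n_zero_pi = as.integer(sum(pi == 0 & !is_case &
                                                           sample$selected))))
}

#' Post-stratify design weights to known phase-I cell totals
#'
#' Rescales the weights of selected subjects within each post-stratum
#' (event indicator crossed with the given variables, by default the
#' surrogate) so that the weighted total equals the phase-I cell count.
#' Variance estimation then treats the post-strata as design strata,
#' mimicking a design that had stratified on the variable from the start.
#'
#' @param weights A `weight_set` from [empirical_probs()] (CC sample).
#' @param cohort Cohort data frame.
#' @param sample The originating `phase2_sample`.
#' @param post_vars Character vector of binary cohort columns crossed with
#'   the event indicator to form post-strata (default `"x_surr"`).
#' @return A `weight_set` (method `"post_stratified"`) whose `strata` are
#'   the post-strata.
#' @export
post_stratify <- function(weights, cohort, sample, post_vars = "x_surr") {
  ps <- build_strata(cohort, post_vars)
  w <- weights$weight
  pi <- weights$inclusion_prob
  for (h in levels(ps)) {
    members <- which(ps == h)
    if (!length(members)) next
    sel <- members[sample$selected[members]]
    tot <- sum(w[sel])
    if (tot == 0) {
      stop("post-stratum '", h, "' has phase-I members but no selected ",
           "subjects; cannot calibrate", call. = FALSE)
    }
    adj <- length(members) / tot
    w[sel] <- w[sel] * adj
    pi[members] <- pi[members] / adj
  }
  structure(
    list(inclusion_prob = pi, weight = w, selected = weights$selected,
         strata = ps, method = "post_stratified", n_zero_pi = weights$n_zero_pi),
    class = "weight_set"
  )
}

#' Compute design weights appropriate to a phase-II sample
#'
#' Convenience dispatcher: empirical stratified weights for SRS/PPS/CC
#' (post-stratified when the design spec asks for it), Samuelsen-type
#' weights for NCC, and their counter-matching analogue for CM.
#'
#' @param cohort Cohort data frame.
#' @param sample A `phase2_sample`.
#' @return A `weight_set`.
#' @export
design_weights <- function(cohort, sample) {
  if (sample$design == "NCC") return(ncc_probs(cohort, sample))
  if (sample$design == "CM") return(cm_probs(cohort, sample))
  ws <- empirical_probs(cohort, sample)
  pv <- sample$spec$post_stratify_vars
  if (!is.null(pv)) ws <- post_stratify(ws, cohort, sample, pv)
  ws
}
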