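#' Specify a phase-II sampling design
#'
#' @param design One of `"SRS"`, `"PPS"`, `"CC"`, `"NCC"`, `"CM"`.
#' @param n_target Planned phase-II sample size.
#' @param strata_vars For PPS/CC: cohort column names crossed with the
#'   event indicator to form sampling strata (may be empty; the event
#'   indicator always participates for PPS/CC).
#' @param controls_per_case Matching ratio m for NCC/CM.
#' @param cm_stratum_var Binary cohort column defining the counter-matching
#'   strata (CM only); defaults to the surrogate `x_surr`.
#' @param post_stratify_vars Optional column names (CC only): after an
#'   unstratified draw, weights are post-stratified on event crossed with
#'   these variables at the analysis stage.
#' @return A `design_spec` object.
#' @examples
#' design_spec("CC", 600, strata_vars = "x_surr")
#' design_spec("CM", 600, cm_stratum_var = "x_surr")
#' @export
design_spec <- function(design = c("SRS", "PPS", "CC", "NCC", "CM"),
                        n_target,
                        strata_vars = character(),
                        controls_per_case = 1L,
                        cm_stratum_var = if (design == "CM") "x_surr" else NULL,
                        post_stratify_vars = NULL) {
  design <- match.arg(design)
  stopifnot(is.numeric(n_target), n_target >= 1, n_target == round(n_target),
            controls_per_case >= 1)
  if (!is.null(post_stratify_vars) && design != "CC") {
    stop("post-stratification is defined for the CC design only", call. = FALSE)
  }
  structure(
    list(design = design, n_target = as.integer(n_target),
         strata_vars = as.character(strata_vars),
         controls_per_case = as.integer(controls_per_case),
         cm_stratum_var = cm_stratum_var,
         post_stratify_vars = post_stratify_vars),
    class = "design_spec"
  )
}

#' Build sampling strata from the event indicator and auxiliary variables
#'
#' Strata are the cross-classification of the event indicator with the
#' listed binary cohort variables, with deterministic, order-stable labels
#' such as `"event=1:x_surr=0"`.
#'
#' @param cohort Cohort data frame.
#' @param strata_vars Character vector of binary cohort columns (may be
#'   empty, giving case/control strata only).
#' @return A factor of stratum labels, one per subject, whose levels
#'   enumerate all combinations (including empty ones).
#' @export
build_strata <- function(cohort, strata_vars = character()) {
  for (v in strata_vars) {
    if (!v %in% names(cohort)) {
      stop("stratification variable '", v, "' not found in cohort", call. = FALSE)
    }
    if (!all(cohort[[v]] %in% c(0L, 1L))) {
      stop("stratification variable '", v, "' must be binary 0/1", call. = FALSE)
    }
  }
  pieces <- c(list(factor(cohort$event, levels = c(0L, 1L))),
              lapply(strata_vars, function(v) factor(cohort[[v]], levels = c(0L, 1L))))
  names(pieces) <- c("event", strata_vars)
  labs <- do.call(paste, c(Map(function(nm, f) paste0(nm, "=", as.character(f)),
                               names(pieces), pieces), list(sep = ":")))
  lev_grid <- expand.grid(lapply(rev(pieces), levels), KEEP.OUT.ATTRS = FALSE)
  lev_grid <- lev_grid[, rev(seq_along(pieces)), drop = FALSE]
  names(lev_grid) <- names(pieces)
  levs <- do.call(paste, c(Map(function(nm, x) paste0(nm, "=", x),
                               names(lev_grid), lev_grid), list(sep = ":")))
  factor(labs, levels = levs)
}

# Largest-remainder apportionment of n across strata of the given sizes.
# Quotas are size * n / sum(size); leftover units go to the largest
# fractional remainders, ties broken by position (stratum label order).
# Allocations never exceed the stratum size.
largest_remainder <- function(sizes, n) {
  stopifnot(n <= sum(sizes))
  quota <- sizes * n / sum(sizes)
  alloc <- floor(quota)
  frac <- quota - alloc
  left <- n - sum(alloc)
  ord <- order(-frac, seq_along(sizes))
  for (j in ord) {
    if (left == 0L) break
    if (alloc[j] < sizes[j]) {
      alloc[j] <- alloc[j] + 1L
      left <- left - 1L
    }
  }
  # pathological case: remaining units go wherever capacity is left
  if (left > 0L) {
    for (j in seq_along(sizes)) {
      add <- min(left, sizes[j] - alloc[j])
      alloc[j] <- alloc[j] + add
      left <- left - add
      if (left == 0L) break
    }
  }
  as.integer(alloc)
}

# Balanced allocation of `target` across cells with the given sizes:
# equal planned shares, cells smaller than their share are taken whole and
# the shortfall is redistributed equally among the remaining cells,
# iterating until the target is met or capacity is exhausted.
# Returns list(alloc, leftover).
allocate_balanced <- function(sizes, target) {
  k <- length(sizes)
  alloc <- integer(k)
  open <- sizes > 0L
  while (target > 0L && any(open)) {
    idx <- which(open)
    share <- integer(k)
    base <- target %/% length(idx)
    extra <- target %% length(idx)
    share[idx] <- base + as.integer(seq_along(idx) <= extra)
    planned <- pmin(alloc + share, sizes)
    consumed <- sum(planned - alloc)
    alloc <- planned
    target <- target - consumed
    newly_full <- open & alloc >= sizes
    if (consumed == 0L) break
    open <- open & !newly_full
  }
  list(alloc = as.integer(alloc), leftover = as.integer(target))
}

new_phase2_sample <- function(cohort, selected, inclusion_prob, stratum,
                              spec, meta = list()) {
  structure(
    list(selected = selected,
         inclusion_prob = inclusion_prob,
         stratum = stratum,
         realized_n = sum(selected),
         design = spec$design,
         spec = spec,
         meta = meta),
    class = "phase2_sample"
  )
}

#' @export
print.phase2_sample <- function(x, ...) {
  cat(sprintf("Phase-II sample: %s design, realized n = %d (planned %d)\n",
              x$design, x$realized_n, x$spec$n_target))
  if (!is.null(x$meta$fallback_cases) && length(x$meta$fallback_cases)) {
    cat(sprintf("  note: %d case(s) used same-stratum fallback sampling\n",
                length(x$meta$fallback_cases)))
  }
  invisible(x)
}

#' Draw a simple random phase-II sample
#'
#' Simple random sampling without replacement: every subject has inclusion
#' probability `n_target / N`.
#'
#' @param cohort Cohort data frame.
#' @param n_target Sample size.
#' @param spec Optional originating [design_spec()].
#' @return A `phase2_sample`.
#' @export
draw_srs <- function(cohort, n_target, spec = design_spec("SRS", n_target)) {
  n <- nrow(cohort)
  if (n_target > n) stop("n_target exceeds cohort size", call. = FALSE)
  sel <- logical(n)
  sel[sample.int(n, n_target)] <- TRUE
  new_phase2_sample(cohort, sel, rep(n_target / n, n),
                    factor(rep("all", n)), spec)
}

#' Draw a probability-proportional-to-size (proportionally stratified) sample
#'
#' Stratified sampling with proportional allocation: each stratum of the
#' event-by-`strata_vars` cross-classification contributes
#' `N_h * n_target / N` subjects (largest-remainder rounding), drawn by
#' simple random sampling within the stratum, so `pi_h = n_h / N_h`.
#'
#' @inheritParams draw_srs
#' @param strata Factor of stratum labels from [build_strata()].
#' @export
draw_pps <- function(cohort, strata, n_target,
                     spec = design_spec("PPS", n_target)) {
  n <- nrow(cohort)
  if (n_target > n) stop("n_target exceeds cohort size", call. = FALSE)
  sizes <- as.integer(table(strata))
  alloc <- largest_remainder(sizes, n_target)
  sel <- logical(n)
  pi <- numeric(n)
  for (h in seq_along(levels(strata))) {
    members <- which(as.integer(strata) == h)
    if (!length(members)) next
    take <- alloc[h]
    if (take > 0L) sel[members[sample.int(length(members), take)]] <- TRUE
    pi[members] <- take / sizes[h]
  }
  new_phase2_sample(cohort, sel, pi, strata, spec,
                    meta = list(planned = alloc, sizes = sizes))
}

#' Draw a (balanced, optionally stratified) case-control sample
#'
#' Half the target size is allocated to cases and half to controls (an odd
#' `n_target` gives the extra unit to the control half). With additional
#' stratification variables each half is split equally across its
#' substrata (balanced design); substrata smaller than their share are
#' taken in full and the shortfall redistributed among the remaining
#' substrata of the same half, then any remainder crosses to the other
#' half, so the planned total is met whenever the cohort permits. The
#' inclusion probability is the realized sampling fraction of the
#' subject's stratum.
#'
#' @inheritParams draw_pps
#' @export
draw_cc <- function(cohort, strata, n_target,
                    spec = design_spec("CC", n_target)) {
  n <- nrow(cohort)
  if (n_target > n) stop("n_target exceeds cohort size", call. = FALSE)
  n_cases <- sum(cohort$event == 1)
  if (n_cases == 0L) stop("case-control sampling requires at least one case",
                          call. = FALSE)
  if (n_cases == n) stop("case-control sampling requires at least one control",
                         call. = FALSE)
  levs <- levels(strata)
  case_levels <- grepl("^event=1", levs)
  sizes <- as.integer(table(strata))
  case_target <- n_target %/% 2L
  ctrl_target <- n_target - case_target
  # allocate within each half, passing any shortfall to the other half
  # (repeat once so a control shortfall can also flow back to cases)
  alloc <- integer(length(levs))
  targets <- c(case = case_target, ctrl = ctrl_target)
  for (pass in 1:2) {
    for (half in c("case", "ctrl")) {
      cells <- if (half == "case") which(case_levels) else which(!case_levels)
      room <- sizes[cells] - alloc[cells]
      res <- allocate_balanced(room, min(targets[[half]], sum(room)))
      alloc[cells] <- alloc[cells] + res$alloc
      short <- targets[[half]] - sum(res$alloc)
      targets[[half]] <- 0L
      other <- if (half == "case") "ctrl" else "case"
      targets[[other]] <- targets[[other]] + short
    }
    if (sum(targets) == 0L) break
  }
  sel <- logical(n)
  pi <- numeric(n)
  for (h in seq_along(levs)) {
    members <- which(as.integer(strata) == h)
    if (!length(members)) next
    take <- alloc[h]
    if (take > 0L) sel[members[sample.int(length(members), take)]] <- TRUE
    pi[members] <- take / sizes[h]
  }
  new_phase2_sample(cohort, sel, pi, strata, spec,
                    meta = list(planned = alloc, sizes = sizes))
}

# Case half of the risk-set designs: all cases when the budget allows,
# otherwise a simple random subsample of floor(n_target/2) cases.
sample_cases <- function(cohort, n_target) {
  cases <- which(cohort$event == 1)
  n_cases <- length(cases)
  if (n_cases == 0L) stop("risk-set sampling requires at least one event",
                          call. = FALSE)
  if (n_target >= 2L * n_cases) {
    list(cases = cases, pi = 1, n_sampled = n_cases)
  } else {
    k <- n_target %/% 2L
    list(cases = sort(sample(cases, k)), pi = k / n_cases, n_sampled = k)
  }
}

#' Draw a nested case-control sample
#'
#' Cases enter with probability 1 when `n_target` is at least twice the
#' number of events, otherwise a simple random subsample of
#' `floor(n_target/2)` cases is taken. For each sampled case, `m` controls
#' are drawn without replacement from its risk set (subjects, cases
#' included, with observed time at least the case's event time, excluding
#' the case itself). Subjects drawn more than once, or drawn as a control
#' and also sampled as a case, appear once, so the realized size may fall
#' below the planned one but never exceeds twice the number of events
#' (at `m = 1`). Inclusion probabilities are filled in by [ncc_probs()].
#'
#' @inheritParams draw_srs
#' @param m Controls per case.
#' @export
draw_ncc <- function(cohort, n_target, m = 1L,
                     spec = design_spec("NCC", n_target, controls_per_case = m)) {
  n <- nrow(cohort)
  cs <- sample_cases(cohort, n_target)
  sel <- logical(n)
  sel[cs$cases] <- TRUE
  short_risk_sets <- 0L
  ord <- cs$cases[order(cohort$obs_time[cs$cases])]
  for (i in ord) {
    rs <- which(cohort$obs_time >= cohort$obs_time[i])
    rs <- rs[rs != i]
    if (length(rs) < m) {
      short_risk_sets <- short_risk_sets + 1L
      take <- rs
    } else {
      take <- rs[sample.int(length(rs), m)]
    }
    sel[take] <- TRUE
  }
  if (short_risk_sets > 0L) {
    warning(short_risk_sets, " risk set(s) smaller than m; took all available",
            call. = FALSE)
  }
  new_phase2_sample(cohort, sel, rep(NA_real_, n),
                    build_strata(cohort), spec,
                    meta = list(sampled_cases = cs$cases, case_pi = cs$pi,
                                m = m, short_risk_sets = short_risk_sets))
}

#' Draw a counter-matched sample
#'
#' As [draw_ncc()], but each sampled case's `m` controls are drawn from
#' the at-risk subjects of the *opposite* stratum of `cm_stratum_var`
#' (typically the surrogate), maximising exposure discordance within
#' matched sets. If the opposite risk set is empty the case's own stratum
#' is used instead and the case is flagged in `meta$fallback_cases`.
#' Inclusion probabilities are filled in by [cm_probs()].
#'
#' @inheritParams draw_ncc
#' @param cm_stratum_var Binary cohort column defining the two strata.
#' @export
draw_cm <- function(cohort, cm_stratum_var, n_target, m = 1L,
                    spec = design_spec("CM", n_target, controls_per_case = m,
                                       cm_stratum_var = cm_stratum_var)) {
  if (!cm_stratum_var %in% names(cohort)) {
    stop("counter-matching variable '", cm_stratum_var, "' not found in cohort",
         call. = FALSE)
  }
  s <- cohort[[cm_stratum_var]]
  if (!all(s %in% c(0L, 1L))) {
    stop("counter-matching variable '", cm_stratum_var, "' must be binary 0/1",
         call. = FALSE)
  }
  n <- nrow(cohort)
  cs <- sample_cases(cohort, n_target)
  sel <- logical(n)
  sel[cs$cases] <- TRUE
  fallback <- integer(0)
  short_risk_sets <- 0L
  ord <- cs$cases[order(cohort$obs_time[cs$cases])]
  for (i in ord) {
    opp <- which(cohort$obs_time >= cohort$obs_time[i] & s == 1L - s[i])
    if (!length(opp)) {
      fallback <- c(fallback, i)
      opp <- which(cohort$obs_time >= cohort$obs_time[i] & s == s[i])
      opp <- opp[opp != i]
      if (!length(opp)) next
    }
    if (length(opp) < m) {
      short_risk_sets <- short_risk_sets + 1L
      take <- opp
    } else {
      take <- opp[sample.int(length(opp), m)]
    }
    sel[take] <- TRUE
  }
  if (short_risk_sets > 0L) {
    warning(short_risk_sets, " risk set(s) smaller than m; took all available",
            call. = FALSE)
  }
  new_phase2_sample(cohort, sel, rep(NA_real_, n),
                    factor(paste0(cm_stratum_var, "=", s)), spec,
                    meta = list(sampled_cases = cs$cases, case_pi = cs$pi,
                                m = m, cm_stratum_var = cm_stratum_var,
                                cm_stratum = s, fallback_cases = fallback,
                                short_risk_sets = short_risk_sets))
}

#' Draw a phase-II sample under any supported design
#'
#' Dispatches on `spec$design` to [draw_srs()], [draw_pps()], [draw_cc()],
#' [draw_ncc()] or [draw_cm()], building strata from `spec$strata_vars`
#' where relevant.
#'
#' @param cohort Cohort data frame.
#' @param spec A [design_spec()].
#' @return A `phase2_sample`.
#' @export
draw_phase2 <- function(cohort, spec) {
  stopifnot(inherits(spec, "design_spec"))
  switch(spec$design,
    SRS = draw_srs(cohort, spec$n_target, spec),
    PPS = draw_pps(cohort, build_strata(cohort, spec$strata_vars),
                   spec$n_target, spec),
    CC = draw_cc(cohort, build_strata(cohort, spec$strata_vars),
                 spec$n_target, spec),
    NCC = draw_ncc(cohort, spec$n_target, spec$controls_per_case, spec),
    CM = draw_cm(cohort, spec$cm_stratum_var, spec$n_target,
                 spec$controls_per_case, spec)
  )
}
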