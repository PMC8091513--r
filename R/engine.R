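failed_record <- function(rep, design) {
  data.frame(rep = rep, design = design, est = NA_real_, se = NA_real_,
             ci_lo = NA_real_, ci_hi = NA_real_, reject = NA,
             realized_n = NA_integer_, converged = FALSE)
}

# deterministic per-design seed offsets: a tiny string hash so that the
# seed stream of a design does not depend on its position in the list
design_seed_offset <- function(name) {
  sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
}

#' The standard design portfolio of the simulation study
#'
#' The eleven phase-II designs compared in the reference tables: SRS; PPS
#' stratified by event alone and crossed with risk factor, confounder or
#' surrogate; CC likewise; NCC; and CM on the surrogate. Optionally adds
#' the CC design post-stratified by the surrogate at the analysis stage.
#'
#' @param n_target Planned phase-II size shared by all designs.
#' @param m Controls per case for NCC/CM.
#' @param include_post_stratified Add `"CC_post_surr"`.
#' @return Named list of [design_spec()]s.
#' @export
standard_designs <- function(n_target, m = 1L, include_post_stratified = FALSE) {
  d <- list(
    SRS = design_spec("SRS", n_target),
    PPS = design_spec("PPS", n_target),
    PPS_risk = design_spec("PPS", n_target, strata_vars = "x_risk"),
    PPS_conf = design_spec("PPS", n_target, strata_vars = "x_conf"),
    PPS_surr = design_spec("PPS", n_target, strata_vars = "x_surr"),
    CC = design_spec("CC", n_target),
    CC_risk = design_spec("CC", n_target, strata_vars = "x_risk"),
    CC_conf = design_spec("CC", n_target, strata_vars = "x_conf"),
    CC_surr = design_spec("CC", n_target, strata_vars = "x_surr"),
    NCC = design_spec("NCC", n_target, controls_per_case = m),
    CM = design_spec("CM", n_target, controls_per_case = m,
                     cm_stratum_var = "x_surr")
  )
  if (include_post_stratified) {
    d$CC_post_surr <- design_spec("CC", n_target, post_stratify_vars = "x_surr")
  }
  d
}

# one design applied to one cohort: draw, weight, fit, test
fit_one_design <- function(cohort, spec, covariates, alpha = 0.05) {
  smp <- draw_phase2(cohort, spec)
  ws <- design_weights(cohort, smp)
  fit <- fit_weighted_cox(cohort, covariates, weights = ws$weight)
  fit <- twophase_variance(fit, weights = ws)
  wt <- wald_test(fit, covariates[1], alpha = alpha)
  list(sample = smp, weights = ws, fit = fit, test = wt)
}

#' Run one simulation scenario end-to-end
#'
#' For each of `B` replications: simulate a phase-I cohort, fit the
#' (unweighted) full-cohort Cox model, then for every design draw the
#' phase-II sample, compute design weights, fit the weighted Cox model
#' with its design-based variance and apply the Wald test. All designs
#' see the same phase-I cohorts (common random numbers), and every
#' replication/design pair has its own deterministically derived seed, so
#' runs are reproducible and design lists can be changed without altering
#' the simulated cohorts.
#'
#' @param config A [scenario_config()].
#' @param designs Named list of [design_spec()]s (e.g.
#'   [standard_designs()]).
#' @param B Number of replications.
#' @param seed Root seed for the scenario.
#' @param covariates Covariates of the fitted Cox model (first one is the
#'   tested biomarker term).
#' @param alpha Wald test level.
#' @param fit_full Also fit the full-cohort model each replication
#'   (design `"full"` in the records; required for efficiency ratios).
#' @return List with `records` (one row per replication and design),
#'   `summaries` (one row per design, via [summarize_performance()]),
#'   and `manifest` (run metadata).
#' @export
run_scenario <- function(config, designs, B, seed,
                         covariates = c("x_bm", "x_conf"),
                         alpha = 0.05, fit_full = TRUE) {
  if (length(designs)) {
    stopifnot(!is.null(names(designs)), all(nzchar(names(designs))))
  } else if (!fit_full) {
    stop("nothing to do: no designs and fit_full = FALSE", call. = FALSE)
  }
  set.seed(seed)
  cohort_seeds <- sample.int(.Machine$integer.max - 1L, B)
  rows <- vector("list", B * (length(designs) + fit_full))
  k <- 0L
  record <- function(rep, design, fit, wt, realized_n) {
    j <- 1L
    data.frame(rep = rep, design = design,
               est = unname(fit$coefficients[j]), se = fit$se[j],
               ci_lo = fit$ci95[j, 1], ci_hi = fit$ci95[j, 2],
               reject = isTRUE(wt$reject), realized_n = realized_n,
               converged = fit$converged)
  }
  for (b in seq_len(B)) {
    cohort <- simulate_cohort(config, seed = cohort_seeds[b])
    if (fit_full) {
      res <- tryCatch(suppressWarnings({
        fit <- fit_weighted_cox(cohort, covariates)
        fit <- twophase_variance(fit, weights = NULL)
        wt <- wald_test(fit, covariates[1], alpha = alpha)
        record(b, "full", fit, wt, nrow(cohort))
      }), error = function(e) failed_record(b, "full"))
      k <- k + 1L
      rows[[k]] <- res
    }
    for (dn in names(designs)) {
      dseed <- (cohort_seeds[b] + design_seed_offset(dn)) %% (.Machine$integer.max - 1L)
      set.seed(dseed)
      res <- tryCatch(
        suppressWarnings(fit_one_design(cohort, designs[[dn]], covariates, alpha)),
        error = function(e) e
      )
      k <- k + 1L
      rows[[k]] <- if (inherits(res, "error")) {
        failed_record(b, dn)
      } else {
        record(b, dn, res$fit, res$test, res$sample$realized_n)
      }
    }
  }
  records <- do.call(rbind, rows[seq_len(k)])
  srs_rec <- if ("SRS" %in% names(designs)) {
    records[records$design == "SRS", , drop = FALSE]
  }
  full_rec <- if (fit_full) records[records$design == "full", , drop = FALSE]
  summarize_safe <- function(dn, rec) {
    tryCatch(cbind(design = dn,
                   summarize_performance(rec, true_beta = config$beta_bm,
                                         srs_records = srs_rec,
                                         full_records = full_rec)),
             error = function(e) {
               message("design '", dn, "' not summarised: ", conditionMessage(e))
               NULL
             })
  }
  summaries <- do.call(rbind, lapply(names(designs), function(dn) {
    summarize_safe(dn, records[records$design == dn, , drop = FALSE])
  }))
  if (fit_full) {
    summaries <- rbind(summarize_safe("full", full_rec), summaries)
  }
  manifest <- list(
    package = "twophasesim",
    version = as.character(utils::packageVersion("twophasesim")),
    B = B, seed = seed,
    designs = names(designs),
    covariates = covariates, alpha = alpha,
    config = unclass(config),
    realized_n = stats::setNames(
      lapply(names(designs), function(dn) {
        r <- records$realized_n[records$design == dn]
        list(mean = mean(r, na.rm = TRUE), min = suppressWarnings(min(r, na.rm = TRUE)),
             max = suppressWarnings(max(r, na.rm = TRUE)))
      }), names(designs))
  )
  list(records = records, summaries = summaries, manifest = manifest)
}

#' Apply a sampling design to a cohort and export the phase-II table
#'
#' Draws one phase-II sample from a cohort (simulated or read from disk)
#' and returns the cohort table augmented with the selection indicator
#' `xi`, the inclusion probability `pi`, the design `weight` and the
#' sampling `stratum`. No model is fitted.
#'
#' @param cohort A cohort data frame (see [as_cohort()] for the schema).
#' @param spec A [design_spec()].
#' @param seed Optional seed for the draw.
#' @return The augmented data frame.
#' @export
apply_design <- function(cohort, spec, seed = NULL) {
  cohort <- as_cohort(cohort)
  if (!is.null(seed)) set.seed(seed)
  smp <- draw_phase2(cohort, spec)
  ws <- design_weights(cohort, smp)
  out <- as.data.frame(cohort)
  out$xi <- as.integer(smp$selected)
  out$pi <- ws$inclusion_prob
  out$weight <- ws$weight
  out$stratum <- as.character(smp$stratum)
  out
}

#' Run a scenario and write all outputs to a directory
#'
#' Writes `records.tsv`, `summaries.tsv` and `manifest.json` under `out_dir`.
#'
#' @inheritParams run_scenario
#' @param out_dir Output directory (created if needed).
#' @return The [run_scenario()] result, invisibly.
#' @export
run_scenario_files <- function(config, designs, B, seed, out_dir,
                               covariates = c("x_bm", "x_conf")) {
  res <- run_scenario(config, designs, B, seed, covariates = covariates)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$records, file.path(out_dir, "records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$summaries, file.path(out_dir, "summaries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
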