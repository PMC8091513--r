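---
title: "Two-phase sampling designs for biomarker studies with survival endpoints"
author: "twophasesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase sampling designs for biomarker studies with survival endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twophasesim)
```

## The problem

A clinical cohort or trial (the *phase-I* sample, size $N$) has follow-up,
an event indicator and cheap covariates for everyone, and stored biological
specimens. A new biomarker is expensive to assay, so it is measured only on
a subsample (*phase II*, size $n$). The question this package addresses is:
**which subjects should be assayed**, and what power does a given choice
buy for detecting the biomarker's effect on the time-to-event endpoint?

Inference reweights phase II back to the cohort: each selected subject $i$
carries a design weight $w_i = 1/\pi_i$, the reciprocal of the
probability $\pi_i = P(\xi_i = 1 \mid X_i, \Delta_i, Z_i)$ of entering the
subsample, and the Cox partial likelihood is maximised with those weights.

## Generative model

Phase-I cohorts are simulated from a directed structure with four binary
covariates:

* a confounder $X_{Conf} \sim \mathrm{Bern}(0.5)$, affecting both the
  biomarker and the hazard;
* the biomarker $P(X_{BM}=1 \mid X_{Conf}) = \mathrm{expit}(a + b\,X_{Conf})$
  — defaults $a=-2$, $b=1.7$ give a *common* marker (marginal prevalence
  27.2%); $a=-4$, $b=1.5$ give a *rare* one (4.7%, i.e. ~5%);
* a surrogate of the biomarker
  $P(X_{Surr}=1 \mid X_{BM}) = \mathrm{expit}(c + d\,X_{BM})$, parameterised
  through its sensitivity and specificity via `surrogate_coefs()`
  (default 0.7/0.7);
* an independent risk factor $X_{Risk} \sim \mathrm{Bern}(0.4)$, affecting
  the hazard only.

Event times follow a Weibull proportional-hazards model,
$T = \left(-\log U / (\lambda e^{\beta'X})\right)^{1/p}$ with shape
$p = 0.9$ and scale $\lambda = 0.1$, so the survival function at $t$ is
$\exp(-\lambda t^{p} e^{\beta'X})$. Random censoring is exponential with
rate $\rho \in \{0, 0.1, 0.4\}$ (≈ 0%, 15%, 50% of subjects randomly
censored), truncated at the administrative end of follow-up $\tau = 2$;
the observed time is $Z = \min(T, C)$ and $\Delta = I(T < C)$. "Censored"
in all reports counts only random censoring before $\min(T, \tau)$, so a
$\rho = 0$ scenario reports 0% even though everyone still at risk is
administratively censored at $\tau$.

The default log hazard ratios are $\beta_{BM} = \beta_{Conf} = \beta_{Risk}
= \log 1.5$, a moderate effect typical of prognostic-marker studies. Under
these defaults a cohort of $N = 2000$ yields about 540 events by $\tau$
without random censoring and about 495 at $\rho = 0.1$ (both closed-form
expectations over the eight covariate cells). All parameters are overridable
through `scenario_config()` or a YAML/JSON file.

What the generator deliberately does **not** emulate: continuous or
multi-level covariates, time-varying effects, competing risks, informative
censoring, or assay measurement error in the biomarker itself. Conclusions
from passing tests therefore speak to design-stage planning under a clean
proportional-hazards world, not to robustness against those violations.

## The five designs

All sampling happens at the end of follow-up; *cases* are subjects with the
event during follow-up, *controls* are event-free at $\tau$.

1. **SRS** — simple random sample; $\pi = n/N$ for everyone.
2. **PPS** — stratified with proportional allocation: stratum $h$ (event
   indicator crossed with any of risk factor / confounder / surrogate)
   contributes $N_h n / N$ subjects. Fractional allocations are rounded by
   **largest remainder** (ties by stratum label order), a documented choice
   since any fixed-size rounding rule must pick one.
3. **CC** — balanced case-control: $n/2$ cases and $n/2$ controls (an odd
   $n$ gives the extra unit to the control half, so the comparison at the
   application scenario's $n = 601$ is well defined). With extra
   stratification variables each half is split equally across its
   substrata; a substratum smaller than its share is taken whole and the
   shortfall redistributed equally among the remaining substrata of the
   same half, then across halves — so the planned $n$ is met whenever the
   cohort permits. If fewer than $n/2$ cases exist, all cases are taken
   and controls fill the rest.
4. **NCC** — nested case-control: each sampled case draws $m$ controls
   without replacement from its risk set $\{j : Z_j \ge t_i\}$ (future
   cases included — required for the Samuelsen weights below). Cases enter
   with probability 1 when $n \ge 2\sum\Delta_i$, otherwise a random
   $\lfloor n/2 \rfloor$ of them; controls are then drawn only at sampled
   cases' event times, keeping the planned 1:$m$ ratio. Duplicate
   selections collapse, so the realized size is at most $2\sum\Delta_i$
   and usually a little below the plan.
5. **CM** — counter-matching on a binary surrogate: controls come from the
   at-risk set of the *opposite* surrogate stratum, maximising exposure
   discordance within matched sets. If the opposite risk set is empty the
   case's own stratum is used and the case flagged
   (`meta$fallback_cases`), avoiding silent sample-size loss; scenarios
   where this matters can exclude those draws.

Ties among event times are handled by using $Z_j \ge t_i$ throughout, so
co-occurring events remain in each other's risk sets; simulated times are
continuous so exact ties have probability zero.

## Weights

* **SRS/PPS/CC** — empirical inclusion probabilities: realized selections
  over stratum size, so weighted stratum totals reproduce the phase-I
  counts exactly.
* **NCC** — Samuelsen-type probabilities: a non-case with observed time
  $Z_j$ escapes selection at each sampled case time $t_i \le Z_j$ with
  probability $1 - m/(R(t_i) - 1)$, and
  $\pi_j = 1 - \prod_i \left(1 - \frac{m}{R(t_i) - 1}\right)$. Cases get
  the case rule's probability. When cases are subsampled, the product runs
  over sampled cases only and the case probability is the realized
  $\lfloor n/2\rfloor / \sum\Delta_i$ — this keeps the computed $\pi$
  equal to the conditional selection frequency of the actual mechanism.
* **CM** — the counter-matching analogue: factors $1 - m/R_s(t_i)$
  accumulate over opposite-stratum sampled cases, with within-stratum
  at-risk counts $R_s$; fallback cases contribute a factor (with the case
  itself excluded from the count) to their *own* stratum, so the formula
  always matches the realized mechanism. Both formulas are validated
  against a Monte-Carlo oracle: selection frequencies over 20,000
  independent redraws of a fixed 20-subject cohort agree with the computed
  $\pi$ within 0.02 per subject. Subjects no sampled case can reach have
  $\pi = 0$ and are excluded from the weighted fit with a logged count —
  an infinite weight has no defensible value.
* **Post-stratification** — a plain CC draw can be calibrated after the
  fact: weights are rescaled within each event-by-surrogate cell so the
  weighted totals match the known phase-I cell counts, mimicking a design
  that had stratified on the surrogate from the start. Variance estimation
  then treats the post-strata as design strata.

Unselected subjects' probabilities are computed and exported too; they
drive the Monte-Carlo oracles and are useful diagnostics.

## Estimation and inference

`fit_weighted_cox()` maximises the weighted Breslow partial
log-likelihood

$$\ell(\beta) = \sum_{i:\Delta_i=1} w_i \Big[\beta'X_i -
\log \sum_{j: Z_j \ge Z_i} w_j e^{\beta'X_j}\Big]$$

by Newton–Raphson with step-halving, declaring convergence when the
largest score component or the relative likelihood change falls below
$10^{-9}$ (at most 50 iterations). Breslow tie handling makes the fit
exactly equal to row duplication for integer weights — one of the suite's
invariant checks, alongside unit-weight agreement with
`survival::coxph()` to $10^{-6}$ on random data sets and invariance of
$\hat\beta$ to rescaling all weights. Separation and absent contrast are
flagged on the result rather than raised, so long simulation runs never
die mid-stream; flagged replications are excluded from summaries and
counted.

The default analysis model follows the minimal adjustment set of the
generative diagram: biomarker plus confounder. The risk factor, although
it shapes the data, is not adjusted for by default (the engine's
`covariates` argument accepts any subset).

The design-based variance adds a phase-II contribution to the inverse
weighted information $I_w^{-1}$, built from per-subject influence terms
$d_i$ (weighted score residuals premultiplied by $I_w^{-1}$):

* stratified designs: $\sum_h (1-f_h)\frac{n_h}{n_h-1}
  \sum_{i \in h}(d_i-\bar d_h)(d_i-\bar d_h)'$ with sampling fraction
  $f_h = n_h/N_h$ — the classical two-phase linearization, vanishing for a
  census;
* NCC/CM: a with-replacement sandwich $\sum_i (1-\pi_i)\, d_i d_i'$
  without stratum-level finite-population correction. The $(1-\pi_i)$
  factor keeps the census limit exact (a subject certain to be selected
  contributes no sampling variance); the estimator is validated the way
  such approximations should be — through its repeated-sampling behaviour:
  across replications the mean estimated variance tracks the empirical
  variance of $\hat\beta_{BM}$ and coverage of the 95% CI stays in the
  0.94–0.98 range for every design at the reference scenario.

A phase-I stratum with a single selected subject loses its correction term
with a warning; a phase-I variance decomposition finer than $I_w^{-1}$ is
out of scope.

## Performance measures

`summarize_performance()` aggregates replication records into: bias,
empirical SE, MSE (identically $\text{bias}^2 + \text{SE}^2$), coverage
and mean length of the 95% CI, power of the 5%-level Wald test,
standardized bias $100 \cdot \text{bias}/\text{SE}_{emp}$, mean realized
$n$, and three ratio measures: the design effect
$\overline{\hat V}_{SRS} / \overline{\hat V}_{design}$ on the model-based
(design) variances, its MSE-based variant, and efficiency versus the full
cohort. Reported design effects exceed 1 for designs more efficient than
SRS. Because the choice between model-based and empirical variances in
the ratio is genuinely open, the empirical-ratio variant is exported as a
diagnostic column (`design_effect_empirical`) rather than silently chosen.

A note on standardized bias: the $100\cdot\text{bias}/\text{SE}$
definition is deliberately sensitive — a design with bias 0.02 and SE 0.17
already scores ~12%. The alternative convention (bias relative to the true
coefficient) gives much smaller numbers for the same fits; consumers of
the summaries should know which is being read.

## The engine

`run_scenario()` shares phase-I cohorts across designs within a
replication (common random numbers, sharpening design contrasts at equal
$B$) and derives a deterministic seed per (replication, design-name) pair,
so adding or removing designs never perturbs the others — an invariant the
suite checks bitwise. Failures inside a replication are recorded and the
run continues. `power_curve()` reuses the same root seed across a grid of
phase-II sizes. `apply_design()` applies any design to a user-supplied
cohort table (schema: `id, obs_time, event, x_bm, x_conf, x_risk, x_surr`)
and exports selection indicators, probabilities and weights without
fitting anything.

```{r example, eval = FALSE}
cfg <- scenario_config(censor_rate = 0.1)
run <- run_scenario(cfg,
                    designs = standard_designs(600),
                    B = 500, seed = 1)
run$summaries[, c("design", "bias", "empirical_se", "power", "design_effect")]
```

## Problem sizes and replication counts

The replication count needed for a target Monte-Carlo accuracy comes from
`burton_replications()`: $B = \lceil (z_{1-\alpha/2}\sqrt{v}/\delta)^2
\rceil$; the study-scale choice ($\delta = 0.0046$, $v = 0.011$) gives
1997 ≈ 2000. The package's own test suite and acceptance script run the
same scenarios at $B = 500$ (and the pure-generator checks at 200
cohorts), a size at which the Monte-Carlo SE of a power estimate is about
2 points and a full design portfolio finishes in well under two minutes —
chosen as the point where every qualitative conclusion is stable while
the suite stays pleasant to run. Any tighter question can simply raise
`B`.

## Known limitations

* Only 1:1 matching is exercised for NCC/CM (the `m` argument is
  structural); case-cohort designs and pilot-data optimal allocation are
  out of scope.
* The counter-matching inclusion-probability formula is the standard
  product-form analogue of Samuelsen's; it is validated against the
  package's own sampling mechanism, not against any external
  implementation of the design.
* The phase-I variance component is approximated by the inverse weighted
  information rather than a term-by-term survey linearization; coverage
  checks, not algebra, are the warrant.
* With heavy censoring and small $n$, matched designs may fail to reach
  the planned size (realized $n \le 2\sum\Delta_i$); the engine reports
  realized sizes so the constraint is visible rather than silent.
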