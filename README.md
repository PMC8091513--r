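# twophasesim

Planning tools for **two-phase biomarker studies with time-to-event
endpoints**: which subjects of an existing cohort should a new, expensive
biomarker be measured on, and how much statistical power does that choice
buy?

The intended users are biostatisticians designing retrospective add-on
studies to clinical cohorts or trials — settings where follow-up, an event
indicator and cheap covariates (a risk factor, a confounder, possibly a
cheap *surrogate* of the biomarker) exist for all *N* subjects (phase I),
but the biomarker can only be assayed on a subsample of *n* (phase II).

## What it computes

The package simulates phase-I cohorts from a Weibull proportional-hazards
model with binary covariates, draws phase-II samples under five designs —

| design | rule |
|---|---|
| `SRS` | simple random sample, π = n/N |
| `PPS` | stratified, proportional allocation (largest-remainder rounding) |
| `CC` | balanced case-control, optionally stratified or post-stratified |
| `NCC` | nested case-control: controls from each case's risk set |
| `CM` | counter-matching on a surrogate: controls from the opposite stratum |

— computes design weights (empirical sampling fractions for SRS/PPS/CC,
Samuelsen-type risk-set inclusion probabilities for NCC and their
counter-matching analogue for CM), and estimates the biomarker effect with
an **inverse-probability-weighted Cox model**: the Breslow partial
likelihood

ℓ(β) = Σ_{i: Δᵢ=1} wᵢ [ β′Xᵢ − log Σ_{j: Z_j ≥ Z_i} w_j exp(β′X_j) ],  wᵢ = 1/πᵢ,

maximised by Newton–Raphson, with a design-based variance (inverse
weighted information plus a phase-II linearization term). A replication
engine aggregates bias, empirical SE, MSE, 95% CI coverage and length,
Wald-test power, standardized bias, and design effects relative to SRS
and to the full cohort, plus power curves over the phase-II sample size.
`burton_replications()` sizes the number of simulation replications for a
target Monte-Carlo accuracy.

Real cohorts can be used too: `read_cohort()` / `apply_design()` draw a
phase-II sample (with probabilities and weights) from any table with
columns `id, obs_time, event, x_bm, x_conf, x_risk, x_surr`.

## Worked example

Compare four designs at a phase-II budget of 600 subjects drawn from
cohorts of 2000 with moderate censoring:

```r
library(twophasesim)

cfg <- scenario_config(censor_rate = 0.1)   # N = 2000, tau = 2, HR_BM = 1.5
run <- run_scenario(cfg,
                    designs = list(
                      SRS     = design_spec("SRS", 600),
                      CC      = design_spec("CC", 600),
                      CC_surr = design_spec("CC", 600, strata_vars = "x_surr"),
                      NCC     = design_spec("NCC", 600)),
                    B = 200, seed = 1)
run$summaries[, c("design", "mean_realized_n", "bias", "empirical_se",
                  "coverage", "power", "design_effect")]
```

```
  design mean_realized_n   bias empirical_se coverage power design_effect
    full        2000.000 -0.013        0.105    0.920 0.960         3.363
     SRS         600.000 -0.006        0.177    0.930 0.580         1.000
      CC         600.000 -0.011        0.162    0.950 0.675         1.246
 CC_surr         600.000 -0.020        0.157    0.945 0.705         1.357
     NCC         550.815 -0.012        0.163    0.950 0.675         1.165
```

Reading the output: every design estimates the true log hazard ratio
(log 1.5 ≈ 0.405) with negligible bias; assaying 600 of 2000 subjects by
balanced case-control recovers 67.5% power (versus 58% for a random
subsample and 96% for assaying everyone), and stratifying the case-control
draw by the surrogate raises it to 70.5% with a design effect of 1.36 —
i.e. a 36% variance advantage over SRS at the same cost. The nested
case-control design collapses duplicate selections, so its realized sample
is ~551 rather than the planned 600.

A thin command-line front end wraps the same functions
(`inst/cli/twophase.R`, subcommands `simulate`, `power`, `sample`), and an
example scenario file ships in `inst/extdata/reference_scenario.yaml`.

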