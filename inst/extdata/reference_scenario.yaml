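# Reference simulation scenario: cohort of 2000 followed to tau = 2,
# common biomarker (~25% prevalence), surrogate with sensitivity =
# specificity = 0.7, hazard ratio 1.5 for biomarker, confounder and risk
# factor, moderate random censoring.
n_phase1: 2000
tau: 2
weibull_shape: 0.9
weibull_scale: 0.1
beta_bm: 0.405465108108164
beta_conf: 0.405465108108164
beta_risk: 0.405465108108164
bm_intercept: -2
bm_slope: 1.7
surr_intercept: -0.847297860387204
surr_slope: 1.69459572077441
p_conf: 0.5
p_risk: 0.4
censor_rate: 0.1
phase2_n: 600
controls_per_case: 1
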