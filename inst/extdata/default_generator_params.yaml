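# Calibrated set-points of the synthetic sepsis-cohort generator.
# These mirror the generator_params() defaults; pass this file to
# `alcsofa simulate --params` as a starting point for overrides.
#
# Calibration targets (cohort marginals): 28-day mortality 21.3%,
# ALC mean 1.07 and SD 0.68 x10^9/L, survivor vs nonsurvivor ALC means
# 1.12 vs 0.90 x10^9/L.  See the methods vignette for the procedure.
n: 10000
beta_severity: 0.20        # log-hazard per SOFA point
beta_immune: 0.35          # log-hazard per unit latent immune deficit
baseline_hazard: 0.00579   # per-day rate at SOFA 6, immune deficit 0
sofa_ref: 6
alc_logmean: -0.102
alc_logsd: 0.583
alc_immune_loading: 0.45
severity_immune_corr: 0.3
component_loading: 0.5
component_probs: [0.45, 0.25, 0.15, 0.10, 0.05]
censor_day: 90
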