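---
title: "Methods: immune-augmented SOFA scoring and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-augmented SOFA scoring and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcsofa)
```

## The scores

SOFA grades six organ systems from first-day worst measurements, 0–4
points each:

| System | Variable (units) | 1 | 2 | 3 | 4 |
|---|---|---|---|---|---|
| Respiratory | PaO₂/FiO₂ (mmHg) | < 400 | < 300 | < 200 + support | < 100 + support |
| Coagulation | platelets (×10³/µL) | < 150 | < 100 | < 50 | < 20 |
| Hepatic | bilirubin (mg/dL) | 1.2–1.9 | 2.0–5.9 | 6.0–11.9 | ≥ 12 |
| Cardiovascular | MAP / vasopressors (µg/kg/min) | MAP < 70 | dopamine ≤ 5 or any dobutamine | dopamine 5–15 or (nor)epinephrine ≤ 0.1 | dopamine > 15 or (nor)epinephrine > 0.1 |
| CNS | Glasgow Coma Scale | 13–14 | 10–12 | 6–9 | < 6 |
| Renal | creatinine (mg/dL) / urine (mL/d) | 1.2–1.9 | 2.0–3.4 | 3.5–4.9 or UO < 500 | ≥ 5.0 or UO < 200 |

The ALC score bins the first-day *minimum* absolute lymphocyte count
(×10⁹/L): 0 for ≥ 1.0, then 1, 2, 3, 4 for [0.78, 1.0), [0.58, 0.78),
[0.36, 0.58) and < 0.36.  ALC-SOFA = SOFA + ALC score, range 0–28.  All
labs except ALC are taken worst-direction (lowest platelets/MAP/GCS/PF,
highest bilirubin/creatinine); ALC is the minimum because lymphopenia is
the exposure of interest.

### Numerical choices at the band edges

Printed clinical grids leave measure-zero gaps; each scorer closes them
once, and the boundary suite tests both sides of every cutoff:

- **Right-open bands on the worst axis.** Bilirubin and creatinine bands
  are [1.2, 2.0), [2.0, 6.0), … so every positive real is scored.
- **Dopamine exactly 5.0 → 2 points**, consistent with the historical
  "≤ 5" wording.
- **PF < 200 without respiratory support caps at 2**: scores 3–4 are
  conditioned on support, and an unsupported patient with a low measured
  ratio does not meet them.
- **ALC exactly 1.0 → 0**: lymphopenia is defined strictly below
  1.0×10⁹/L (1,000 cells/µL).
- **Missing organ inputs score 0 and are flagged** in a per-patient
  `flags` string (`strict_missing = TRUE` turns this into an error).
  Missing ALC is always an error at scoring time — it is an exclusion
  criterion, not a zero — so a silent 0-point immune score can never be
  produced.
- **Vasopressor doses count only when given ≥ 1 h**; an absent duration
  flag is treated as qualifying (permissive default), since most tabular
  extracts do not carry duration.

Units are fixed (mg/dL, ×10³/µL, ×10⁹/L, µg/kg/min, mmHg, mL/day) and
never auto-converted; silent unit conversion is the classic severity-score
bug, and refusing it makes unit errors loud.

## Exclusion cascade

`apply_exclusions()` applies, in order: repeat admission; undeterminable
28-day status (neither death ≤ 28 d nor follow-up ≥ 28 d); age < 18; ICU
stay ≤ 24 h; missing first-day ALC; ALC outside Tukey's fences
(Q1 ± 1.5·IQR, type-7 interpolated quartiles, computed on the patients
remaining after the earlier steps).  The order is part of the contract —
the fences see only the post-exclusion distribution — and the attrition
log records each step.  Fences are two-sided; on a right-skewed
(lognormal-like) ALC distribution the rule flags essentially the upper
tail, and on realistic synthetic cohorts it removes roughly 4–5% of
patients.  That is the literal behaviour of the rule on skewed data, not a
defect.  Missing values never trigger a rule other than their own
(`missing_alc`); an unknown age, for instance, is retained.

## Discrimination statistics

- **AUROC** is computed in its Mann–Whitney form from midranks (ties get
  half credit), identical to brute-force pair counting, which the test
  suite verifies on hundreds of random tied fixtures.
- **DeLong's test** uses per-patient placement values (the fraction of
  opposite-class patients ranked below each patient), their empirical
  variances/covariances scaled by the class sizes, and a two-sided normal
  test on the AUROC difference.  The implementation uses the O(N log N)
  midrank identity; the suite checks it, exactly, against a
  straight-from-definition O(mn) reimplementation.  A score compared with
  itself returns z = 0, p = 1; zero difference-variance with unequal
  AUROCs is refused as degenerate.
- **NRI/IDI on calibrated risks.**  Because ALC-SOFA ≥ SOFA pointwise,
  raw-score movement is degenerate (every patient "up"), so each score is
  first calibrated to event probabilities with a univariate logistic fit
  (`fit_score_risk()`; complete separation is an error advising category
  collapse).  Continuous NRI is P(up|event) − P(down|event) +
  P(down|nonevent) − P(up|nonevent) with ties moving neither way; IDI is
  the difference in discrimination slopes.
- **Bootstrap CIs** are patient-level, unstratified, percentile-method
  (B = 1000 by default, matching the study convention; smoke tests use
  smaller B purely for speed).  The calibration is refitted inside every
  resample; single-outcome-class resamples are redrawn and counted; a
  statistic failing on > 10% of resamples is an error.  Percentile rather
  than BCa was chosen because the interval target is a simple
  location-type statistic and percentile is what validation studies
  conventionally report.
- **Operating points** use Youden's J over observed score values
  (predicted positive when score ≥ threshold; ties resolved to the lowest
  threshold), reporting sensitivity, specificity, PPV, NPV, PLR, NLR.
  The threshold rule is pluggable in principle; Youden is the default
  because no alternative rule is conventionally stated for this use.

## Survival analysis

`km_estimate()` is the product-limit estimator with the standard tie
convention (patients censored at an event time count as at risk there);
`logrank_test()` builds the observed-minus-expected statistic with the
full hypergeometric covariance on G − 1 groups.  Both are checked against
`survival::survfit()`/`survdiff()` as independent oracles.
`class_curves()` stratifies the combined score into 5-point classes
([0,5), …, [20,28]); empty classes are dropped and listed.  Cox screening
fits univariate proportional-hazards models per covariate (Breslow ties),
passes those with Wald p < 0.05 into one joint refit (no stepwise
removal), and reports HRs with 95% CIs.  The partial-likelihood
optimisation is delegated to `survival::coxph` — the contract is the
optimum, not the optimiser.  Constant covariates are skipped with a log
entry; non-convergence is an error naming the covariate.

## The synthetic cohort: a stated world

The generator draws two correlated standard-normal axes per patient:
organ-failure severity *z* and immune deficit *w* (correlation 0.3 — the
two processes are related but distinct, which is precisely the condition
under which an immune component can add prognostic information).  Each of
the six organ components gets an ordinal score through a shared-loading
model (loading 0.5 on *z*, common cutpoints from marginal probabilities
0.45/0.25/0.15/0.10/0.05, giving a SOFA distribution with median 6 and
IQR ≈ 4–9, in the range reported for sepsis cohorts), and the raw
measurement is then drawn uniformly *inside* the band of that score, so
re-scoring recovers the intended component exactly (band inversion — a
tested invariant, which is why missingness is opt-in rather than default).
ALC is lognormal with a negative loading on *w*; death times are
exponential with rate

  baseline_hazard · exp(β_sev · (SOFA − 6) + β_imm · w),

administratively censored at day 90.

Defaults are calibration set-points, fixed once against the published
cohort marginals and not revisited: β_sev = 0.20/point, β_imm = 0.35,
baseline_hazard = 0.00579/day, alc_logmean = −0.102, alc_logsd = 0.583
with immune loading 0.45.  At these values a large simulated cohort shows
28-day mortality ≈ 21.3%, ALC ≈ 1.07 ± 0.68×10⁹/L, and survivor vs
nonsurvivor ALC means ≈ 1.12 vs 0.88 (the published split is 1.12 vs
0.90; 0.88 is the closest joint fit — pushing the nonsurvivor mean up
pulls the survivor mean off its target).  The generator emulates
*marginals and directional structure*, not a real ICU: no time-series, no
correlated comorbidity structure, no informative censoring, exponential
(constant-hazard) event times, and AUROC levels higher than observational
studies report (the latent model is cleaner than reality).  A green test
therefore establishes that the pipeline detects structure it should
detect and stays calibrated when that structure is absent — not that any
clinical effect size is reproduced.

## Testing the DeLong test's size: what counts as a null

A type-I-error (size) measurement requires the null hypothesis — equal
population AUROCs — to actually hold.  Switching off only the immune
hazard (β_imm = 0) does **not** produce that null: organ severity still
drives mortality, the ALC component becomes pure noise, and adding noise
to a predictive score strictly lowers its population AUROC, so rejections
in that configuration are correct power against a (slightly) false null
(the suite pins this down: the combined score's AUROC falls below the
organ score's there).  The size check therefore runs under the true null
β_sev = β_imm = 0, where both scores' AUROCs are exactly 0.5; over 500
simulated cohorts of n = 2000 the acceptance suite requires the empirical
size to sit within 5% ± 2.5.  (At this sample size, with ~300 events and
heavily tied integer scores, DeLong is known to run very slightly
liberal; a 1000-cohort study during development measured ≈ 6%.)

## Parameter recovery

Because the generator's hazard is exactly proportional in SOFA and *w*,
the joint Cox fit on (SOFA total, *w*) is correctly specified and its
log-HRs are consistent for (β_sev, β_imm); the acceptance suite requires
both within ±0.1 at n = 5000 across 20 seeds.  The univariate SOFA fit is
*not* used for recovery: omitting *w* both attenuates (non-collapsibility)
and confounds (corr(z, w) > 0) the marginal coefficient.

## Known limitations

- Serial/hourly SOFA, ΔSOFA-based sepsis diagnosis, and pediatric scores
  are out of scope; the package scores first-day records only.
- Categorical NRI, time-dependent ROC, BCa intervals and calibration
  plots are not implemented.
- The Cox stage reports no proportional-hazards diagnostics; the screen
  is a reproduction of a published selection procedure, not a recommended
  model-building strategy.
- The scored-CSV `flags` column does not round-trip the distinction
  between "no flags" and "missing" (both read back as empty); flags are
  informational, not analytic inputs.
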