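# alcsofa

Severity scoring and score-validation tooling for sepsis cohorts: the
six-system **SOFA** (Sequential Organ Failure Assessment) score, an
immune-augmented variant (**ALC-SOFA**) that adds a 0–4 point bin score for
the first-day minimum absolute lymphocyte count (ALC), and the complete
statistical pipeline needed to compare the two scores on patient-level data.

## Who this is for

Researchers validating ICU severity scores on retrospective cohorts.  SOFA
quantifies organ dysfunction (respiratory, coagulation, hepatic,
cardiovascular, CNS, renal; 0–4 points each, total 0–24) but carries no
immune-function component, although sepsis-induced lymphopenia marks the
immunosuppressed phenotype that drives late mortality.  ALC-SOFA adds a
lymphocyte bin score — 0 for ALC ≥ 1.0×10⁹/L, then 1–4 for bins
[0.78, 1.0), [0.58, 0.78), [0.36, 0.58) and < 0.36×10⁹/L — giving a 0–28
combined score.  The package implements:

- **Scoring** — all six SOFA component scorers and the ALC score, with
  explicit band closures at the printed-cutoff gaps and auditable handling
  of missing components (`compute_sofa()`, `compute_alc_sofa()`,
  `score_cohort()`).
- **Cohort filters** — the exclusion cascade (repeat admissions,
  undeterminable 28-day status, under-18, ICU stay ≤ 24 h, missing ALC,
  ALC outside Tukey's fences) with a full attrition log
  (`apply_exclusions()`, `tukey_fences()`).
- **Discrimination** — AUROC (Mann–Whitney form), the DeLong paired test
  for correlated AUROCs, logistic risk calibration, continuous NRI, IDI,
  bootstrap percentile CIs, and Youden-index operating points
  (sensitivity/specificity/PPV/NPV/PLR/NLR).
- **Survival** — Kaplan–Meier product-limit curves, the log-rank test,
  5-point score-class curves, horizon mortality, and univariate →
  multivariate Cox screening with a p < 0.05 entry rule (Breslow ties).
- **Synthetic cohorts** — a generator with two correlated latent axes
  (organ-failure severity and immune deficit), band-inverted raw
  measurements (re-scoring reproduces the intended component scores
  exactly), and survival whose hazard depends on both axes, calibrated to
  published sepsis-cohort marginals (21.3% 28-day mortality, ALC
  1.07 ± 0.68×10⁹/L).

## Worked example

```r
library(alcsofa)

# one ICU patient: moderate organ failure plus marked lymphopenia
patient <- data.frame(
  patient_id = "icu-0042", age = 71, sex = "female",
  pf_ratio = 210, respiratory_support = TRUE,
  platelets = 95, bilirubin = 2.4, map = 63,
  dopamine = 0, dobutamine = 0, epinephrine = 0, norepinephrine = 0.08,
  gcs = 13, creatinine = 1.6, urine_output_24h = 900,
  alc = 0.52, icu_los_hours = 96, repeat_admission = FALSE,
  time_days = 21, event = TRUE
)
compute_alc_sofa(patient)
#>   respiratory coagulation hepatic cardiovascular cns renal sofa_total flags
#> 1           2           2       2              3   1     1         11
#>   alc_score alc_sofa_total
#> 1         3             14
```

PaO₂/FiO₂ 210 scores 2; platelets 95 score 2; bilirubin 2.4 scores 2;
norepinephrine 0.08 µg/kg/min scores 3; GCS 13 scores 1; creatinine 1.6
scores 1 — SOFA 11.  ALC 0.52×10⁹/L falls in the [0.36, 0.58) bin (3
points), so ALC-SOFA is 14.

```r
# synthetic cohort -> exclusions -> scores -> score comparison
gen <- generate_cohort(generator_params(n = 5000, seed = 42))
flt <- apply_exclusions(gen$cohort)
scored <- score_cohort(flt$cohort)
y <- horizon_label(scored$time_days, scored$event, 28)

delong_compare(scored$alc_sofa_total, scored$sofa_total, y)
#> AUROC ALC-SOFA 0.767 vs SOFA 0.762, DeLong p = 0.04657

reclassification(scored$alc_sofa_total, scored$sofa_total, y,
                 b = 200, seed = 42)
#> NRI 0.216 (95% CI 0.065-0.357), IDI 0.0064 (95% CI 0.0002-0.0144)

class_curves(scored$alc_sofa_total, scored$time_days, scored$event)
#> log-rank across 5 score classes: chi2 1889.2, p = 0
```

The combined score discriminates 28-day mortality slightly but
systematically better than the organ score alone (higher AUROC, positive
NRI/IDI), and mortality rises steeply across the 5-point score classes —
the pattern the pipeline is designed to detect.  On this synthetic run the
fences step excluded 239/5000 patients: Tukey's fences on a right-skewed
lymphocyte distribution flag the upper tail (see the methods vignette).

## Command line

```sh
alcsofa simulate --n 10000 --seed 7 --out cohort.csv --truth truth.csv
alcsofa filter   --in cohort.csv --out kept.csv --attrition attrition.json
alcsofa score    --in kept.csv --out scored.csv
alcsofa evaluate --in scored.csv --horizons 7,28,90 --boot 1000 --seed 7 --out report.json
alcsofa run      --config config.yaml    # filter -> score -> evaluate
```

(`inst/exec/alcsofa`; run with `Rscript` if not on PATH.)  `run` writes
`scored.csv`, `km_curves.csv`, `attrition.json` and a `report.json` that
validates against `inst/schema/report-schema.json`; identical config plus
seed reproduces the report byte for byte.

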