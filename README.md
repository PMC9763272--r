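# rmkpredict

Predicting discharge upper-limb muscle strength from baseline
robot-measured kinematics in subacute stroke.

## The problem

After a stroke, most survivors begin rehabilitation with impaired arm
function, and clinicians must set discharge goals with very little
quantitative information. Planar end-effector rehabilitation robots
record every reaching movement a patient makes, so the movements
themselves can serve as objective baseline biomarkers. This package
implements, as a tested and reusable pipeline, an analysis that predicts
the **Motricity Index (MI)** of the affected upper limb at discharge —
the total score and its elbow-flexion and shoulder-abduction sub-items —
from **robot-measured kinematic (RMK) metrics** extracted at admission
from point-to-point reaching movements in four directions. It is aimed
at rehabilitation researchers who want to study or extend
kinematics-based outcome prediction without access to the original
patient records: a synthetic cohort generator reproduces the statistical
structure the analysis assumes, so every stage runs end to end.

## The model

For each movement direction (A = away from the body, B and D = lateral,
C = toward the body, in a reference frame mirrored onto the lesion
side), two metrics are extracted from the recorded trajectory
(N samples, coordinates centred on the central target):

- **Movement Path Error** — the mean distance from the straight line
  joining the central and peripheral targets. With targets on the
  coordinate axes, `MPE = (1/N) Σ |y[k]|` for direction D and
  `(1/N) Σ |x[k]|` for directions A and C; it is 0 for a perfectly
  straight movement.
- **Mean Movement Speed** — `MS = (1/N) Σ √(vx[k]² + vy[k]²)`.

The predictive features are MPE_A, MPE_C, MPE_D and MS_B. After
standardizing age, stroke-onset time and the metrics, each discharge
outcome is modelled by covariate-adjusted least-squares regression

    MI(T2) ~ age + sex + onset + MI(T1) + MPE_A + MPE_C + MPE_D + MS_B

with backward elimination of non-significant kinematic predictors, and
validated two ways: a 75/25 **split-sample validation** (with a
chi-square / ANOVA / Mann-Whitney balance battery plus a four-group
Kruskal-Wallis check under Bonferroni correction) and **leave-one-out
cross-validation** (n fits, each predicting its held-out record).
Because the MI is a discrete scale (six classes per sub-item; total =
sum of three sub-items + 1, maximum 100), continuous predictions are
snapped to the nearest valid score before rank-correlation evaluation.
The evaluation panel reports RMSE, MAE, their normalized variants, R²,
adjusted R², and Spearman's r with a strength rubric. The published
single-predictor models — e.g. `MI_UL(T2) = 32.50 − 11.99 · MPE_C(T1)`
on standardized MPE_C — are available via `predict_published()`.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/04_loocv.R`; each stage writes its tables under `results/`.
Running all four stages prints (seed 20229):

```
$ Rscript analysis/01_simulate.R
Simulating 66 patients (seed 20229, 200 Hz, 0.14 m targets)...
Wrote results/cohort: 66 patients, 264 trajectory files.
Age 66.0 +/- 11.3 y; 74% male; 62% right-affected; onset 14.9 +/- 12.5 d.

$ Rscript analysis/02_extract_features.R
Max relative deviation from generator targets: MPE_C 1.25%, MS_B 1.18%

$ Rscript analysis/04_loocv.R
LOOCV over 66 records (66 fold fits per outcome):
MI_ELBOW: R2 0.721, RMSE 3.36 (RMSE_n 10%), Spearman r 0.823 (strong); final MPE_C beta -4.04 (generating -4.89)
MI_SHOULDER: R2 0.428, RMSE 4.61 (RMSE_n 14%), Spearman r 0.588 (moderate); final MPE_C beta -5.51 (generating -4.26)
MI_UL: R2 0.803, RMSE 6.19 (RMSE_n 6.3%), Spearman r 0.907 (strong); final MPE_C beta -13.09 (generating -11.99)
```

Reading: the simulated cohort reproduces the intended demographic
marginals; features re-extracted from the trajectory files agree with
the generator's targets to ~1% (200 Hz discretization); and on this
cohort the leave-one-out procedure selects the path error toward the
body (MPE_C) as a significant predictor for all three outcomes, with
each final-model coefficient within sampling error of the coefficient
the cohort was generated from. Interactively, the same machinery is a
few calls:

```r
library(rmkpredict)
cohort <- generate_cohort(generator_config(seed = 1))
loocv  <- run_loocv(cohort)
loocv$outcomes$UL$report     # pooled out-of-fold evaluation panel
predict_published("UL", 0)   # 32.5
```

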