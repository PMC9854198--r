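# radsurv

CT radiomics and deep Cox survival modelling of tumour progression risk
after EGFR-TKI therapy in advanced non-small-cell lung cancer (NSCLC).

Patients with EGFR-mutant NSCLC respond very unevenly to first-line
tyrosine-kinase inhibitors: median progression-free survival (PFS) sits
near a year, but individual patients progress anywhere from weeks to
several years. radsurv implements, end to end, a pipeline that predicts
each patient's PFS from pretreatment CT and clinical data and converts the
prediction into an interpretable *risk-of-progression period*:

1. **Radiomics** — resample the CT volume to 1 mm³, Z-score normalise,
   decompose into eight undecimated Coiflet-1 wavelet subbands
   (LLL…HHH), and extract **593 features** per tumour ROI: 14 histogram +
   22 GLCM + 16 GLRLM + 12 LBP features on each of the nine image sets,
   plus 17 shape features (including compactness₂ = 36πV²/A³, the
   sphere-normalised roundness).
2. **Two-step feature selection** — univariate screens at p < 0.1
   (Cox proportional hazards for radiomic features, chi-squared on
   good/poor tumour control for clinical features), then sequential
   forward selection with a cross-validated concordance scorer.
3. **DeepSurv** — a feed-forward network h(x) estimating the log relative
   hazard, trained full-batch with Adam on the average negative log Cox
   partial likelihood
   `L = -(1/N_E) Σ_{i:event} [h_i − log Σ_{T_j ≥ T_i} exp h_j] + λ‖W‖²`,
   with a Breslow baseline S₀(t) giving personalized curves
   `S(t|x) = S₀(t)^{exp h(x)}`. Three variants are trained: clinical,
   radiomic, combined.
4. **Evaluation** — Harrell C-index, time-dependent ROC/AUC at 3, 12, 18
   and 24 months, log-rank tests, and paired bootstrap model comparison.
5. **Risk-of-progression period** — a Weibull reference curve
   `S_ref(t) = exp(−(t/λ)^k)` fitted through the four horizon-specific
   optimal (Youden) thresholds; the interval in which a patient's
   personalized curve first dips below the reference is their risk period
   (<3, 3–12, 12–18, 18–24 or >24 months).

Because the clinical cohort this pipeline targets is not publicly
distributable, radsurv ships a **synthetic cohort generator**: tumour
phantoms whose shape (compactness) and intensity texture (local
homogeneity, IDMN) carry planted prognostic signal, clinical covariates
with realistic marginals, and Weibull proportional-hazards PFS times with
a ~11.5-month median regime. All ground truth is logged, so recovery of
the planted structure is testable.

## Worked example

```r
library(radsurv)

cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 270, seed = 101),
  grid_shape = c(48, 48, 48),
  seeds = list(split = 1L, folds = 1L, train = 1L, bootstrap = 99L),
  bootstrap_B = 300)

run <- run_pipeline(cfg, progress = TRUE)
print(run$metrics, n = 12)
```

```
   model    c_index horizon   auc sensitivity specificity threshold
 1 clinical   0.683       3 0.763       0.909       0.588     0.867
 2 clinical   0.683      12 0.741       0.727       0.692     0.564
 3 clinical   0.683      18 0.703       0.684       0.654     0.464
 4 clinical   0.683      24 0.677       0.682       0.692     0.484
 5 radiomic   0.608       3 0.634       0.545       0.75      0.851
 6 radiomic   0.608      12 0.618       0.485       0.821     0.512
 7 radiomic   0.608      18 0.661       0.474       0.846     0.403
 8 radiomic   0.608      24 0.649       0.841       0.462     0.552
 9 combined   0.714       3 0.779       0.636       0.809     0.837
10 combined   0.714      12 0.775       0.545       0.923     0.444
11 combined   0.714      18 0.781       0.526       0.962     0.302
12 combined   0.714      24 0.717       0.477       0.923     0.251
```

The combined model's test concordance (0.71) exceeds the radiomic-only
(0.61) and clinical-only (0.68) variants, and its time-dependent AUCs
(0.72–0.78) dominate the single-view models at every horizon — the planted
signal lives partly in the images and partly in the clinical table, and
only the combined model sees both.

```r
run$reference_curve
#> <reference_risk_curve> shape k = 1.007, scale lambda = 24.70 months
table(run$risk_report$risk_period)
#>  <3 months  3-12 months 12-18 months 18-24 months   >24 months
#>         32           10            1            0           38
```

Each test patient's personalized curve is compared with the reference:
patients whose curve is below the reference from the start are flagged
"<3 months" (imminent progression risk), patients whose curve never dips
below it are ">24 months". Plots:

```r
autoplot(run$models$combined)                       # training curves
autoplot(Filter(Negate(is.null), run$roc$combined)[[1]])  # ROC at 3 months
autoplot(run$reference_curve)                       # reference risk curve
```

Lower-level entry points mirror the pipeline stages:
`generate_phantom()`, `generate_cohort()`, `extract_features()`,
`screen_radiomic()` / `screen_clinical()`, `sequential_forward_select()`,
`deepsurv_train()` / `predict()` / `predict_survival_curve()`,
`time_dependent_roc()`, `bootstrap_compare()`, `fit_weibull_reference()`,
`risk_period_report()`. Fitted objects have broom-style `tidy()` and
`glance()` methods.

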