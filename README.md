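# thyrosig

Thyroid homeostasis signatures and outcome modelling in stress
cardiomyopathy (Takotsubo syndrome, TTS).

Abnormal thyroid function is common at TTS admission, and thyroid
hormones sensitize the myocardium to the catecholamine surge that drives
the syndrome. `thyrosig` is for clinical researchers and biostatisticians
who want to ask, from an admission thyroid panel (TSH, FT4, FT3), whether
a cohort's thyroid state carries prognostic information — and to do so
with reproducible, tested machinery rather than ad-hoc scripts.

The pipeline:

1. **Calculated parameters of thyroid homeostasis** per patient:
   thyroid's secretory capacity
   `SPINA-GT = β_T (D_T + TSH)(1 + K41·TBG + K42·TTR)·FT4 / (α_T · TSH)`
   (pmol/s; only off levothyroxine), sum activity of peripheral
   deiodinases
   `SPINA-GD = β31 (K_M1 + FT4)(1 + K30·TBG)·FT3 / (α31 · FT4)` (nmol/s),
   Jostel's TSH index `JTI = ln TSH + 0.1345·FT4`, the thyrotroph
   resistance index `TTSI = 100·TSH·FT4 / FT4_upper`, and the thyroid
   feedback quantile-based index
   `TFQI = F_FT4(FT4) − (1 − F_TSH(TSH)) ∈ [−1, 1]`.
2. **Endotype classification** into normal function, TACITUS
   (non-thyroidal illness, reduced FT3), type 2 allostatic load (elevated
   FT4 with non-suppressed TSH), primary thyrotoxicosis and primary
   hypothyroidism, with fixed rule precedence and configurable reference
   ranges.
3. **Cluster discovery**: deterministic multi-start PAM (k-medoids) in
   the z-standardized TSH×FT4 plane, k selected by average silhouette
   width, and three-cluster solutions labelled TSLT/TSHT/TSNT (low /
   high / normal thyroid output) by their position relative to the
   cohort-median SPINA-GT.
4. **Survival stack**: phi- and Youden-optimal marker cutoffs,
   Kaplan–Meier curves with log-rank tests, univariable → stepwise
   minimal multivariable Cox models (entry p < 0.10, stay p < 0.05), and
   a frailty-adjusted hierarchical variant; plus the in-hospital
   composite complication endpoint.
5. **A synthetic registry cohort** (`simulate_cohort()`) matched to the
   published cohort structure, so the whole pipeline runs and is testable
   without patient-level data, including null and planted-effect
   generators for calibration and recovery experiments.

## Worked example

```r
library(thyrosig)
library(dplyr)

cohort <- simulate_cohort(seed = 3) |>
  add_thyroid_indices() |>
  add_endotype()
cohort_flow(cohort)
#> # A tibble: 1 × 5
#>   n_screened n_cluster n_full_panel n_survival n_cluster_survival
#>        <int>     <int>        <int>      <int>              <int>
#> 1        690       288          169        568                238

cl <- cluster_thyroid(cohort, k_range = 2:6, seed = 3) |>
  label_clusters(cohort)
cl
#> thyroid-signature clusters: k = 3  avg silhouette = 0.454
#> # A tibble: 3 × 5
#>   cluster   tsh   ft4 label     n
#>     <int> <dbl> <dbl> <chr> <int>
#> 1       1 0.753  21.1 TSHT     62
#> 2       2 4.93   13.5 TSLT     60
#> 3       3 1.21   13.3 TSNT    166
```

690 synthetic admissions were screened; 288 carry the complete TSH+FT4
panel required for clustering and 169 the full panel including FT3. The
silhouette rule selects three clusters whose medoids (actual patients, in
original units) separate a high-output signature (suppressed-to-normal
TSH at 21 pmol/L FT4), a low-output signature (TSH ≈ 4.9 mIU/L at
low-normal FT4) and a normal-output majority.

```r
cohort <- add_cluster(cohort, cl)
kaplan_meier(cohort, "cluster_label")
#> Kaplan-Meier estimate, n = 238, stratified by cluster_label
#> log-rank chi-squared = 2.11 (df 2), p = 0.35

survival_cutoffs(cohort, markers = c("ft3", "spina_gd")) |>
  select(marker, cutoff_phi, direction_phi)
#> # A tibble: 2 × 3
#>   marker   cutoff_phi direction_phi
#> 1 ft3            4.85 less
#> 2 spina_gd      28.9  less

cox_models(cohort) |> tidy() |>
  filter(model == "multivariable") |>
  select(term, hr, conf_low, conf_high, p_value)
#> # A tibble: 3 × 5
#>   term                   hr conf_low conf_high  p_value
#> 1 ft3                 0.819    0.676     0.993 0.0420
#> 2 atrial_fibrillation 2.72     1.36      5.46  0.00486
#> 3 initial_ef          0.951    0.927     0.977 0.000196
```

The cutoff directions read: FT3 *below* 4.85 pmol/L (and deiodinase
activity below 28.9 nmol/s) predicts death — the low-T3 signature of
critical illness. The stepwise minimal Cox model retains FT3 (HR 0.82
per pmol/L: higher FT3 is protective), atrial fibrillation (HR 2.7) and
initial ejection fraction (HR 0.95 per percent), recovering the effects
the generator plants.

`autoplot()` methods draw the cluster scatter with medoids marked and
the Kaplan–Meier step curves; `run_pipeline()` chains all stages and
writes the result tables as CSV/JSON artifacts
(`Rscript scripts/thyrosig.R --simulate --seed 7 --out results/run7`).

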