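# readervar

Observer variability and diagnostic accuracy analysis for multi-reader
diagnostic imaging studies with ordinal confidence annotations — motivated by
slice-level adhesion detection on abdominal cine-MRI, where a panel of
radiologists reviews sagittal cine slices, places bounding boxes at suspected
adhesions with a 1–5 confidence score, and a consensus panel defines the
slice-level reference standard.

The package is for biostatisticians and imaging researchers running (or
re-analyzing) such reader studies. It covers the full pipeline:

* **Scoring** — box annotations → slice × observer ordinal scores (0 = not
  annotated, otherwise the maximum box confidence), binarized at each
  reader's stated clinical-significance threshold (score ≥ t, confidence c
  read as 20c%).
* **Agreement** — Fleiss' κ = (P̄ − P̄ₑ)/(1 − P̄ₑ) with pooled-category
  chance agreement for reader groups; Cohen's κ for repeat readings of one
  reader; unanimity percentage agreement (share of slices where *all*
  readers in a group give the same call); the conventional
  poor/slight/fair/moderate interpretation bands.
* **Inference** — case-resampling bootstrap percentile CIs (slices
  resampled, panel fixed); observer-permutation tests for group differences
  (readers re-partitioned, p = (1 + #{|Δ*| ≥ |Δ|})/(1 + n_perm));
  a two-way (reader × case) bootstrap z-test for group AUC differences.
* **ROC analysis** — per-reader curves with one point per confidence level
  used; trapezoidal AUC (= tie-corrected Mann–Whitney probability);
  diagonally averaged group curves (averaging along lines perpendicular to
  the chance diagonal); operating-point extraction at a target sensitivity.
* **Synthetic studies** — a seeded equal-variance binormal latent-model
  generator (discrimination d, shared case effect with per-reader loading,
  session noise) with closed-form AUC Φ(d/√(2(1+σ²))), including a canonical
  fixture that mirrors the motivating design: 10 patients, 61 slices, 19
  positive, 15 readers (3 consensus), 5 repeat readers,
  experience-linked discrimination.

Everything user-facing takes and returns tibbles; fitted objects have
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods.

## Worked example

```r
library(readervar)

study <- simulate_benchmark_study(seed = 1)
study
#> <simulated_study: 10 patients, 61 slices (19 positive), 15 observers, 406 annotations>

report <- run_analysis(study$annotations, study$profiles, study$reference,
                       n_boot = 500, n_perm = 999, seed = 1)
report
#> <reader_study_report>
#>   61 slices, 15 observers, seed 1
#>   inter-observer agreement:
#> # A tibble: 7 × 4
#>   group         fleiss_kappa pct_agreement mean_auc
#>   <chr>                <dbl>         <dbl>    <dbl>
#> 1 consensus           0.470           75.4   NA
#> 2 high-adhesion       0.140           60.7    0.721
#> 3 high-cine           0.337           47.5    0.774
#> 4 high-year           0.330           39.3    0.766
#> 5 low-adhesion        0.147           27.9    0.708
#> 6 low-cine            0.0528          45.9    0.652
#> 7 low-year            0.0461          50.8    0.660
```

Reading the table: the consensus panel agrees most (κ 0.47, "moderate");
the high-experience groups reach "fair" agreement (κ ≈ 0.33) while the
low-experience groups sit near chance (κ ≈ 0.05, "slight"); and the
diagonally averaged group AUCs run from 0.65 (low-cine) to 0.77 (high-cine),
with no AUC for the consensus group because it defined the reference
standard. `report$comparisons` holds the permutation p-values and AUC
z-tests behind statements like "the high-year group agrees significantly
more than the low-year group"; `report$intra_observer` the repeat-reader
Cohen's κ:

```r
dplyr::select(report$intra_observer, observer_id, cohen_kappa, pct_agreement)
#> # A tibble: 5 × 3
#>   observer_id cohen_kappa pct_agreement
#>   <chr>             <dbl>         <dbl>
#> 1 obs02            0.815           96.7
#> 2 obs03            0.649           88.5
#> 3 obs04            0.568           83.6
#> 4 obs07            0.849           98.4
#> 5 obs15           -0.0596          88.5

glance(report$roc_curves[["obs07"]])
#> # A tibble: 1 × 3
#>     auc n_thresholds observer_id
#>   <dbl>        <int> <chr>
#> 1 0.736            6 obs07

operating_point(report$roc_curves[["obs07"]], 0.9, interpolate = TRUE)
#> # A tibble: 1 × 2
#>   sensitivity specificity
#>         <dbl>       <dbl>
#> 1         0.9       0.241
```

`autoplot(report)` draws the per-reader ROC curves with the diagonally
averaged group curves, one panel per experience axis; `write_report(report,
dir)` emits the tables as CSV plus a JSON run manifest, and
`analyze_study_dir()` runs the whole pipeline from a directory of
`annotations.csv` / `observers.csv` / `reference.csv`. A thin CLI wrapper
with `simulate` and `analyze` subcommands lives at `inst/cli/readervar.R`.

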