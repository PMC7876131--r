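# powerstate

Classify brain states from resting-state fMRI by encoding each scan as the
degree distribution of its thresholded correlation network.

## The problem and who this is for

Functional connectivity studies often require an anatomical atlas and a
priori seed regions. An alternative is to work atlas-free: flatten a 4D
scan (`X × Y × Z × T`) to a voxel-by-time matrix, link every voxel pair
whose Pearson correlation

    r(x1, x2) = ( mean(v1·v2) − mean(v1)·mean(v2) ) / ( σ1·σ2 )

exceeds a threshold (0.7 by default), and summarize the whole brain by its
**degree distribution** — how many voxels have each number of links. Across
experimental states (the motivating design: four anesthesia × strain states
HS/HW/LS/LW, 20 rats each), these distributions follow power laws
`count(k) ≈ c·k^(−γ)` with state-dependent exponents, but the exponent
alone classifies poorly. powerstate implements the full pipeline for
researchers who want the stronger, bin-level analysis:

- **encoding**: 4D volume → voxel×time matrix → chunked thresholded
  Pearson network → degree distribution (`flatten_volume`,
  `build_degree_vector`, `encode_sample`);
- **power laws**: single and broken (two-exponent) log-log least-squares
  fits with AIC comparison (`fit_single_power`, `fit_double_power`,
  `compare_aic`);
- **feature selection**: two-phase chi2 (ChiMerge-style) discretization of
  degree bins with consistency checking — bins merged to one interval are
  dropped (`chi2_select`);
- **classification**: C4.5 decision tree (gain-ratio splits, pessimistic
  pruning) under stratified tenfold cross-validation with macro
  one-vs-rest ROC (`build_tree`, `tenfold_cv`);
- **state transitions**: a transformation matrix of per-bin ridge
  regressions mapping one state's distributions toward another state's
  mean, judged by the tree (`fit_tm`, `evaluate_transition`,
  `four_level_circuit`);
- **graph metrics**: average/max shortest-path length and clustering
  coefficient of the voxel network (`path_stats`,
  `clustering_coefficients`);
- **synthetic data**: generators for labeled power-law degree cohorts and
  planted-cluster 4D volumes, since the original scans are not public
  (`generate_degree_cohort`, `generate_fmri_cohort`).

## Worked example

```r
library(powerstate)

profiles <- list(state_profile("HS", 1.6, 500), state_profile("HW", 1.9, 500),
                 state_profile("LS", 2.2, 500), state_profile("LW", 2.5, 500))
cohort <- generate_degree_cohort(profiles, n_per_state = 20, seed = 42)
ft  <- feature_table(cohort, n_bins = 200)
sel <- chi2_select(ft$x, ft$labels, delta = 0.05)
sel
#> chi2 discretization: 47/200 attributes selected (inconsistency 0.0000, sigLevel0 = 1e-05)

cv <- tenfold_cv(ft$x[, sel$selected], ft$labels, seed = 42)
cv
#> 10-fold cross-validation: accuracy 0.900, macro one-vs-rest ROC area 0.921
#> Per-class AUC:
#>     HS     HW     LS     LW
#> 0.9333 0.8188 0.9308 1.0000
#> Pooled confusion:
#>      predicted
#> truth HS HW LS LW
#>    HS 18  2  0  0
#>    HW  2 15  3  0
#>    LS  0  1 19  0
#>    LW  0  0  0 20

fit_single_power(state_mean_distribution(cohort, "LS"))
#> Single power law: count = 439.6 * k^(-2.123)  [n = 21, rss = 1.061, AIC = -56.68]
```

Reading the numbers: the chi2 phase kept 47 of 200 degree bins (mostly low
degrees, where the states' expected counts differ most); the C4.5 tree
classifies the four states with pooled accuracy 0.90 and macro one-vs-rest
ROC area 0.92 under tenfold cross-validation; and the LS state's average
distribution is fit by a power law with exponent 2.12, close to its
generating value 2.2.

The same flow runs end-to-end with artifact persistence via
`run_pipeline(pipeline_config(...))`, or from a shell through
`inst/scripts/run_pipeline.R`. NIfTI scans enter through
`encode_sample("scan.nii.gz")` or the `nifti_paths` field of
`pipeline_config()`.

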