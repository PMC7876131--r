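---
title: "Classifying brain states from degree-distribution power laws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying brain states from degree-distribution power laws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerstate)
```

## The model

powerstate implements a whole-brain, atlas-free encoding of resting-state
fMRI. A 4D scan (three spatial dimensions by time) is flattened to a
voxel-by-time matrix; every voxel pair is scored by the Pearson correlation

$$r(x_1, x_2) = \frac{\overline{v(x_1,t)\,v(x_2,t)} -
  \overline{v(x_1,t)}\;\overline{v(x_2,t)}}{\sigma(x_1)\,\sigma(x_2)},$$

computed with population (1/N) standard deviations; and two voxels are
declared *linked* when $r$ strictly exceeds a threshold, 0.7 by default.
The *degree* of a voxel is its number of links, and the scan's encoding is
its **degree distribution**: the counted number of voxels at each degree
$k \ge 1$. Across anesthesia/strain states (the motivating design is four
states — high/low isoflurane crossed with a hypertensive-rat disease model
and its control strain, 20 animals per state) these distributions are well
described by power laws $\mathrm{count}(k) \approx c\,k^{-\gamma}$ with
state-dependent exponents.

The exponent alone is a weak classifier, so the pipeline instead treats the
degree bins themselves as features:

1. **chi2 discretization / feature selection** picks the degree bins whose
   counts discriminate the states;
2. a **C4.5 decision tree** (gain-ratio splits on continuous attributes,
   pessimistic pruning) classifies samples from the selected bins, scored by
   stratified tenfold cross-validation with a macro one-vs-rest ROC area;
3. a **transformation matrix** (TM) of per-bin ridge regressions maps one
   state's distributions toward another state's mean, and the tree judges
   whether the simulated transition "arrived".

Shortest-path length and clustering-coefficient summaries of the voxel
network are provided for network characterization alongside the classifier.

## Design choices in the encoding

* **Strict threshold, positive correlation only.** A link requires
  $r > 0.7$, not $\ge$; anti-correlated voxels never link. Both follow the
  definition of linking as *exceeding* a positive-correlation threshold;
  the threshold is a parameter throughout.
* **Degree-0 voxels are excluded from the distribution by default.** On a
  whole-head grid, background/air voxels dominate the zero bin and carry no
  network information; log-log plots of degree versus counted number start
  at $k = 1$ anyway. `include_zero = TRUE` restores the zero bin, in which
  case counts sum to the voxel total.
* **Masking by temporal variance.** Voxels with variance at or below
  `var_eps` (default `1e-12`) are treated as empty and form no links; an
  explicit logical mask can be supplied as well. A correlation against a
  zero-variance series is undefined (`NA`), never silently 0.
* **Chunked correlation.** Degrees are computed in blocks of voxel rows
  against the standardized matrix, so memory stays proportional to
  `block_size` times the voxel count rather than its square; the result is
  block-size invariant, which the tests assert, and the full
  $64 \times 64 \times 11 \times 525$ scan shape flattens to its
  $45{,}056 \times 525$ matrix in well under a second.
* **Raster order** is x-fastest (R's native array order), recorded in a
  voxel index so row numbers map back to coordinates. Order affects only
  bookkeeping, never the distribution.

## Power-law fitting and model comparison

Fits are ordinary least squares in $(\log k, \log \mathrm{count})$: the
exponent is minus the slope. This matches how the distributions are read
off log-log plots; maximum-likelihood fitting of discrete power laws is a
deliberate non-goal. The broken ("double") power law fits two unconstrained
segments on either side of a breakpoint chosen by grid search over observed
degrees with at least three points per side.

Models are compared by the Gaussian-residual AIC,
$n \ln(\mathrm{rss}/n) + 2p$, with $p = 3$ for the single law (slope,
intercept, residual variance) and $p = 5$ for the broken law. Ties favour
the single law. A residual sum at the floating-point floor is treated as an
exact fit (AIC $-\infty$), so nested exact fits resolve to the simpler
model rather than to rounding noise.

**Known limitation.** Because the breakpoint is chosen by search, the
broken law's best-of-grid improvement under a *true* single power law
behaves like the maximum of many correlated $\chi^2_2$ draws, which
typically exceeds the AIC penalty difference of 4. In simulation the AIC
comparison therefore prefers the broken law for most single-truth noisy
replicates, while on true two-regime data it is essentially always right.
The test suite measures exactly this (and records the single-truth failure
rather than hiding it): treat "double preferred" as weak evidence unless
the rss improvement is large. Penalizing the searched breakpoint
explicitly (e.g. BIC or a sup-F calibration) is future work.

The per-state exponent is best read from the **state-average distribution**
(`state_mean_distribution()`), which averages counts over a state's samples
with zeros included and drops degree bins seen in fewer than half the
samples. Per-sample tails are zero-truncated Poisson counts — bins with
expectation below 1 appear only when they are nonzero — which flattens a
naive per-sample log-log fit; averaging with zero-fill and requiring
majority support removes that bias. With the default generator settings
(amplitude 500, 200 bins, Poisson noise, 20 samples/state) the averaged fit
recovers exponents 1.6 and 2.4 within 0.15.

## The chi2 algorithm

`chi2_select()` is a two-phase, ChiMerge-style discretizer driven by

$$X^2 = \sum \frac{(f_0 - f_e)^2}{f_e},$$

with $f_e$ the expected cell count under independence of interval and
class; adjacent intervals merge while their pairwise $X^2$ stays below the
critical value at the current significance level (degrees of freedom =
classes − 1, ties to the leftmost pair).

* **Phase 1** walks a ladder of decreasing significance levels — default
  $\{0.5, 0.1, 0.05, 0.01, 0.005, 0.001, 10^{-4}, 10^{-5}\}$ — re-merging
  every attribute from scratch, and stops before the first level whose
  discretized table exceeds the inconsistency tolerance `delta`
  (default 0.05): the fraction of samples in duplicated discretized
  patterns beyond each pattern's majority class.
* **Phase 2** refines attribute by attribute: each keeps descending the
  ladder on its own while table-wide consistency holds.
* Attributes merged to a single interval are irrelevant to the class and
  are dropped — the discretization *is* the feature selection.

The reference description leaves the ladder, `delta`, and stopping details
unstated; the defaults above follow the chi2-algorithm literature and are
configurable. Degree distributions have ragged support, so cohorts are
tabulated into a rectangular table (default bins 1–200) with zero fill
before selection.

## C4.5 and its evaluation

The tree inducer is a faithful small C4.5 for complete continuous
attributes: candidate thresholds are midpoints between consecutive distinct
values; a candidate is admissible only if its information gain reaches the
mean gain over candidates (C4.5's guard against many weak thresholds);
among admissible candidates the best **gain ratio** — gain divided by the
entropy of the child-size proportions — wins, ties to the smallest
threshold. Entropy is in bits (base 2; the reference formula leaves the
base unstated). Values equal to a threshold route left ($\le$). Growth
stops at purity, `min_leaf`, or no admissible split; trees are then
simplified by pessimistic error pruning at confidence 0.25 (the
Clopper–Pearson upper limit on the leaf error rate, Quinlan's default CF),
which provably never increases the node count. Missing-value fractioning
is excluded: feature tables are complete after zero fill.

Cross-validation is stratified tenfold under a fixed seed. The reported
"ROC" is the macro-averaged one-vs-rest AUC of the pooled held-out leaf
probabilities (computed with pROC); the reference leaves its multi-class
aggregation undefined, and macro one-vs-rest is the conventional choice.
A training fold can lack a rare class entirely; its probability column is
then 0 for that fold's predictions, and a warning flags classes with fewer
members than folds. The tree consumes the **raw counts** of the selected
bins by default — discretized interval codes are a documented alternative —
since the selected-bin counts preserve more ordering information.

## The transformation matrix

For a transition from an original state to a target state, the dependent
variable of every one of the $p$ (default 200) regression equations is the
*target-state mean count* of that bin — a constant across the $n$ training
samples (default 15 of 20, leaving 5 for testing) — regressed on the full
original-state bin vectors. With $n \ll p$ the system is underdetermined,
so the rows are estimated by ridge regression (default penalty 1.0, the
intercept unpenalized); at `ridge = 0` the minimum-norm pseudo-inverse
solution is used as the documented limit. Two consequences worth stating
plainly:

* applying the fitted TM to the training mean reproduces the target mean
  (exactly at `ridge = 0`, to numerical precision with the default);
* with an intercept the optimum puts nearly all the constant response into
  the intercept, so the fitted map is strongly attracted toward the target
  mean regardless of input. That is what makes "complete transitions"
  (all 5 held-out samples classified as the target state) achievable, and
  it is also why the TM should be read as a state-level, not sample-level,
  simulation. `intercept = FALSE` forces the weights to carry the map.

Transformed counts are clamped at zero (counts cannot be negative) after
the affine map; the map is exactly affine before clamping, which the tests
assert. The four-level "circle" scheme chains four TMs around the state
cycle and classifies after every hop, so classification error can only
compound along the circle.

## Graph metrics

`path_stats()` and `clustering_coefficients()` summarize the thresholded
network: average and maximum shortest-path length over connected ordered
pairs (pairs in different components have no finite path and are excluded;
whether the average should instead be over per-vertex means is unstated in
the reference, and pair-averaging is the documented choice), and the
standard average clustering coefficient $C = \frac{1}{N}\sum_i C_i$ with
$C_i = 2e_i / (k_i(k_i-1))$, zero for $k_i < 2$, averaged over the $N$
voxels with at least one link (configurable to all voxels). The reference
prints the average as $C = 1/(N \sum C_i)$, which is read here as a
typesetting slip for the standard form. Both metrics are computed with
igraph and verified in the tests against an adjacency-matrix oracle
(matrix-power BFS, $\mathrm{diag}(A^3)$ triangle counts).

## The synthetic-data generators

No public accession exists for the original scans, so the package ships
two generators that emulate the statistical structure the analysis
assumes, at the two levels the pipeline consumes:

* `generate_degree_cohort()` draws labeled degree distributions directly:
  state $s$ has expected count $c_s k^{-\gamma_s}$ at degree $k$, with
  Poisson count noise (counts are non-negative integers, and Poisson is the
  minimal count-noise model; `noise = "none"` rounds half-to-even for exact
  closed-form checks). The default study conditions are four states, 20
  samples per state, amplitude 500, 200 degree bins; "moderate" exponent
  separation is $\{1.6, 1.9, 2.2, 2.5\}$ and "strong" separation
  $\{1.2, 1.8, 2.4, 3.0\}$, spanning the exponent range over which the
  states' average curves visibly separate on a log-log plot.
* `generate_fmri_cohort()` plants correlated voxel clusters in small 4D
  volumes: cluster voxels are $\sqrt{\rho}\,z + \sqrt{1-\rho}\,\epsilon$
  around a shared latent series $z$, giving expected pairwise correlation
  $\rho$ (`within_corr`, required to exceed the 0.7 linking threshold);
  background voxels are independent noise. The planted assignment is
  returned, so tests can check the encoding against ground truth — a
  $k$-voxel cluster yields $k$ voxels of degree $k-1$. Default test grids
  are small (about $8 \times 8 \times 2 \times 60$) so everything is
  desk-scale; the full scan shape is supported and exercised only in the
  flattening check. The timepoint count is a free parameter (the reference
  reports both 525 and 300 for its scans).

What the generators do **not** emulate: BOLD hemodynamics and autocorrelated
scanner noise, motion, anesthesia physiology, spatial smoothness of real
brains, or the spatial layout of functional systems. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's machinery is
correct and that it separates states whose degree distributions differ as
modeled — not that real scans of these states are classifiable at the same
ROC.

## Numerical conventions and degenerate inputs

* Seeded operations (`generate_*`, `tenfold_cv`, `transition_protocol`,
  `run_pipeline`) restore the caller's RNG state and are bitwise
  reproducible for equal seeds.
* Tie-breaks are deterministic everywhere: leftmost interval pair in
  ChiMerge, smallest threshold in splits (within a $10^{-10}$ gain-ratio
  tolerance so floating-point noise cannot flip a tie), smallest breakpoint
  in the double fit, simpler model on AIC ties.
* Fewer than 3 (single) / 6 (double) distinct degrees, zero-variance
  series, empty graphs, dimension mismatches, and transitions toward
  states the tree never saw all raise immediate, specific errors.
* Degree-cohort bins whose realized count is zero are dropped from the
  long form and restored as zeros by `feature_table()`.

## Problem sizes used by the checks

The shipped tests and the acceptance script run the full pipeline at the
study conditions (80 samples, 200 bins — a few seconds per run), oracle
comparisons at up to 200 voxels / 50 graph vertices, and 100-replicate
fitting simulations at 200 bins; these sizes give stable statistics while
keeping the whole suite to a couple of minutes on one core.
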