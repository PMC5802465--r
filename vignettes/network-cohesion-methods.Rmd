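---
title: "Methods: sliding-window network cohesion and its inference pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window network cohesion and its inference pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcohesion)
```

## The model

`netcohesion` quantifies how tightly the nodes of a predefined brain
network co-fluctuate at each moment of a naturalistic-viewing fMRI scan,
and compares that quantity between two groups of subjects.

The core statistic is the **Network Cohesion Index (NCI)**. For a
network of $n$ nodes and a time window $w$, let
$r_{ij}(w)$ be the Pearson correlation between the signals of nodes
$i$ and $j$ inside the window, and
$z_{ij}(w) = \operatorname{atanh} r_{ij}(w)$ its Fisher
transform. The NCI is the one-sample $t$-statistic of the
$m = n(n-1)/2$ transformed correlations against zero:

$$
\mathrm{NCI}(w) \;=\; \frac{\bar z(w)}{s_z(w) / \sqrt{m}},
$$

with $\bar z$ the sample mean and $s_z$ the sample standard deviation.
The NCI is large when the pairwise correlations are consistently
positive; it penalizes both weak and heterogeneous coupling. It is
invariant under affine rescaling of any node's signal and under
relabelling of the nodes (`nci_t()`, `pairwise_correlations()`).

Windows slide along the scan on a fixed grid (`make_window_grid()`):
after trimming `trim` onset volumes, windows of `window` TRs advance by
`step` TRs. The defaults — 165 volumes at TR = 3 s, `trim = 5`,
`window = 10`, `step = 1` — give 160 usable volumes and 151 windows,
i.e. 90 % overlap between consecutive windows.

```{r grid}
make_window_grid(160, window = 10, step = 1, trim = 5)
```

## Group inference per window

For each window, the two groups' NCI values are compared with a
Wilcoxon rank-sum test in its normal approximation with midranks and
tie correction (`ranksum_z()`). The reported `Z` is oriented
**control minus patient**: positive `Z` means controls show higher
cohesion. The rank-sum test is used because per-window NCI
distributions across subjects are short-tailed but skewed, and because
a rank statistic is invariant under any monotone transform of the NCI.

`groupdiff_series()` runs this test across windows for NCI, for the
windowed rating trace, or for network activity amplitude, and controls
the false discovery rate across windows with Benjamini–Hochberg
(`stats::p.adjust`). By default the tested span is the **central
lag-truncated span**: the windows that survive every lag of the
cross-correlation analysis below (131 of 151 windows under the default
±10 lags), so that window-wise inference and lagged inference refer to
the same data. `span = "full"` tests all windows.

## Lagged cross-correlation with the rating

To ask whether group differences in cohesion precede or follow group
differences in a continuous emotion rating, the two group-difference
`Z` series are cross-correlated at lags $-L,\dots,L$ windows
(`L = 10` by default). Every lag is evaluated on the same central span
of the `y` series (`shift_align()`), so all 21 correlations use equally
many points (131 by default) and are comparable. Positive lag means the
NCI difference **precedes** the rating difference. The correlation is
Spearman's $\rho$ with midranks (`spearman_rho()`), again for
robustness to the saturating shape of rank-sum `Z`.

Because overlapping windows make the series strongly autocorrelated,
parametric $p$-values would be far too small. The null is instead built
by **phase randomization** (`phase_randomize()`): each subject's NCI
series is Fourier transformed, the phases of the non-DC, non-Nyquist
frequencies are replaced by fresh uniform phases with conjugate
symmetry, and the series is inverted. Surrogates preserve each series'
mean, variance and full amplitude spectrum — hence its autocorrelation —
while destroying any alignment with the rating. For each of `n_boot`
iterations the rank-sum `Z` series is recomputed from the surrogate
cohort and correlated with the observed rating difference; the
two-sided bootstrap $p$ at each lag is
$(\#\{|\rho_0| \ge |\rho_{\mathrm{obs}}|\} + 1)/(n_\mathrm{boot} + 1)$,
BH-corrected over the 21 lags (`crosscorr_bootstrap()`). Iterations in
which the surrogate `Z` series is constant (so $\rho$ is undefined) are
discarded and counted in the `n_discarded` attribute.

## Symptom association and classification

`symptom_corr_series()` correlates patients' per-window NCI with a
symptom subscale score (Spearman, across patients, per window), with BH
correction over windows; windows with fewer than four testable patients
or constant scores are flagged `untestable` rather than silently
dropped.

`knn_repeated_cv()` classifies subjects from their concatenated NCI
time courses (one feature per network × window; 302 features under the
defaults) with a $k$-nearest-neighbour classifier ($k = 10$, Euclidean
distance, unweighted majority vote, an even split resolved by the
single nearest neighbour) under stratified 5-fold cross-validation
repeated `reps` times. Chance level is assessed by label permutation
(`permutation_test()`): the full repeated-CV accuracy is recomputed
under `n_perm` random label assignments and
$p = (\#\{\mathrm{perm} \ge \mathrm{obs}\} + 1)/(n_\mathrm{perm}+1)$.
The distance matrix is computed once and reused across folds,
repetitions and permutations.

## The synthetic-cohort generator

No empirical data ship with the package; every stage is validated
against simulated cohorts with *planted, recoverable* structure
(`sim_config()`, `generate_cohort()`). The generator uses a
**shared-factor model**: node $i$ of a network follows

$$
x_i(t) \;=\; \sqrt{c_g(t)}\, f(t) \;+\; \sqrt{1 - c_g(t)}\,\varepsilon_i(t),
$$

where $f$ is a network-wide factor, $\varepsilon_i$ are independent
node-specific innovations, and $c_g(t) \in [0, 1)$ is the group- and
time-dependent coupling profile. Under this model the expected pairwise
correlation inside a window equals the local coupling $c$, so planted
coupling levels are directly checkable from recovered correlations.
Innovations are white by default; `ar_phi` switches them to AR(1) with
unit marginal variance, which leaves per-window expectations intact
while adding realistic temporal smoothness.

Group differences are planted by adding an offset to $c$ for one group
over chosen window spans (`coupling_profile()`,
`window_span_offset()`). The continuous rating is generated at 10 Hz on
a 0–21 scale (seven labelled levels at three intensities): a base curve
driven by the coupling dynamics, a group-specific component shifted by
`rating_lag` windows, and smooth noise (a moving-average of white
noise), so that the cross-correlation stage has a known ground-truth
lag. A symptom link plants a linear relation between a chosen
subscale and NCI at one window, recoverable by
`symptom_corr_series()`. Ground truth is returned alongside the cohort
and written to `ground_truth.json` by `write_cohort()`.

What the generator does *not* emulate: hemodynamic convolution, spatial
structure within nodes, scanner drift, or motion artefacts. It is a
parameter-recovery harness for the statistics, not a forward model of
BOLD physiology.

```{r sim}
cfg <- sim_config(n_per_group = 6, seed = 1)
cohort <- generate_cohort(cfg)$cohort
grid <- make_window_grid(160)
nci <- cohort_nci(cohort, default_networks()$ES, grid)
dim(nci$values)
```

## Numerical choices

* **Correlation clipping.** `fisher_z()` maps $|r| \ge 1$ to
  $\pm(1 - 10^{-10})$ with a warning; an exact $\pm 1$ (possible in
  short windows of nearly collinear signals) would otherwise give an
  infinite $z$ and poison the window mean.
* **Degenerate windows.** A node with zero variance in a window makes
  its correlations undefined: the window's NCI is `NA` and flagged in
  `$degenerate`. If all pairwise $z$ are identical ($s_z = 0$), the NCI
  is $\pm\infty$ with the sign of $\bar z$. Rank-sum comparisons
  exclude non-finite values per window and report the per-group counts
  actually used; windows with fewer than two usable subjects per group
  are `untestable`.
* **Central truncation.** All lags share the span
  $(L+1),\dots,(N-L)$ of the `y` series, rather than letting the
  overlap length vary with lag; correlations across lags are then
  computed from equally sized, identical-target samples.
* **Ties.** Rank-sum `Z` uses the standard tie-corrected variance;
  Spearman uses midranks. Both are tested against `wilcox.test()` /
  `cor.test()` as oracles.
* **Permutation/bootstrap $p$-values** always use the add-one
  convention, so no reported $p$ is ever zero and the floor
  $1/(n+1)$ is explicit.
* **Reproducibility.** All randomness goes through
  `withr::with_seed()`; `run_pipeline()` derives one substream per
  stage from the master seed, so disabling a stage does not shift the
  randomness of the others, and reruns are bit-identical.

## Limitations

* The rank-sum `Z` series saturates where a planted effect is strong,
  which flattens the cross-correlation ridge near its peak; lag
  localization from moderate cohorts is coarse (a few windows), though
  the direction and boundary lags are recovered reliably.
* BH control is across windows (or lags) within one analysis, not
  across networks, measures and analyses jointly.
* The kNN tie-break and stratified folds are deliberately simple; the
  classifier is a fixed reference implementation, not a tuned model.
* The generator's coupling profile is piecewise-constant per window
  span; gradual coupling changes are not modelled.
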