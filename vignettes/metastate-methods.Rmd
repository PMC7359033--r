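---
title: "Detecting brain meta-state transitions without priors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting brain meta-state transitions without priors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Time-varying functional connectivity research suggests that whole-brain
activity moves through a sequence of transiently stable network
configurations - *meta-states* - and that the switches between them track
cognitive events: in movie-watching fMRI they align with narrative event
boundaries, and at rest they plausibly mark the arrival of new thoughts.
Most existing detectors need priors: states learned from a group watching
the same stimulus, states visited earlier by the same person, or a
pre-specified number of events. This package implements a detector that
needs none of these. It operates on a single run from a single participant
and makes only one structural assumption: that a meta-state is a
neighborhood in the space of network configurations which activity leaves
abruptly when a transition occurs.

## The detection model

The input is a network-activation timeseries: a $T \times K$ matrix $X$
(typically $T = 900$ s at TR $= 1$ s and $K = 15$ networks, obtained by
dual regression of group-ICA spatial maps; `dual_regression()`), smoothed
with a centered moving average of span 5 s (`smooth_networks()`).

1. **Embedding.** $X$ is reduced to two dimensions with t-SNE at
   perplexity 30 (`embed_timepoints()`). In the embedded space,
   meta-stable epochs form contiguous, worm-like segments; unstable
   passages scatter.
2. **Step distance.** Successive embedded points $y_t$ are compared with
   the squared Mahalanobis distance
   $$d_t = (y_{t+1} - y_t)^\top \Sigma^{-1} (y_{t+1} - y_t),$$
   where $\Sigma$ is the empirical covariance of the $T$ embedded points
   (`step_distance()`).
3. **Ensemble.** t-SNE is stochastic, so steps 1-2 are repeated (100
   times by default) and the step distance vectors averaged elementwise
   (`ensemble_step_distance()`). A percentile bootstrap over the
   per-repetition vectors gives a per-timepoint confidence ribbon.
4. **Detection.** Transitions are local maxima of the mean step distance
   vector with peak prominence at least 0.06 (`find_transitions()`);
   meta-stable timepoints are troughs whose width at half prominence is at
   least 10 samples (`find_metastable()`).

Averaging *step vectors* rather than coordinates is what makes the
ensemble well-posed: any two t-SNE runs differ by (at least) an arbitrary
rotation, reflection and scale, but the Mahalanobis form absorbs every
invertible affine map of the plane, so each repetition's step vector lives
on a common scale. The test suite verifies this invariance to $10^{-8}$
over random invertible maps.

The prominence criterion (height of a peak above the higher of its two
bounding saddles) is preferred over a plain height threshold because it
judges each peak against its own neighborhood. The published calibration
selected 0.06 as the value at which roughly 80% of all step distance
values fall below the 5th percentile of transition-associated values;
`calibrate_mpp()` reproduces that procedure on any collection of step
distance vectors.

## Tunable parameters

| Parameter | Default | Units | Where | Why |
|---|---|---|---|---|
| `span_s` | 5 | s | `smooth_networks` | close to HRF time-to-peak; 1-9 s give comparable rates |
| `perplexity` | 30 | - | embedding | moderate default; requires $T > 3\times$ perplexity |
| `n_iter` | 100 | - | ensemble | stabilizes the mean step vector |
| `max_iter` | 350 | - | t-SNE optimizer | see "Numerical choices" |
| `mpp` | 0.06 | Mahalanobis units | `find_transitions` | calibrated prominence threshold |
| `min_width_samples` | 10 | samples | `find_metastable` | persistently stable periods only |
| `lag_window_s` | (3, 6) | s | feature sampling | canonical HRF lag, sampled backwards |
| `censor_window_s` | 3 | s | censoring cascade | boundary bin $\pm$ 1 |
| `clip_censor_s` | 6 | s | censoring cascade | clip-onset artifacts |
| `trim_epochs` | 5 | epochs | conformity | run onset/offset effects |
| `n_boot` | 1000 | - | all bootstraps | percentile CIs and bootstrap ratios |

## Validation machinery

**Feature alignment.** For movie-like data with annotated features, the
mean feature value in the 3-6 s window *before* each transition and each
meta-stable onset (working backwards along the HRF) is averaged per
participant; a paired $t$ across participants is converted to the
proportion of feature variance explained, $\eta^2 = t^2/(t^2 +
\mathrm{df})$ (`feature_alignment()`). The window is the inclusive integer
bin range $[t-6, t-3]$; onsets whose window leaves the run or is fully
censored are skipped, uniformly in censored and uncensored analyses.
Nested features are disentangled by a censoring cascade
(`censor_cascade()`): event boundaries censor everything else in a 3-s
window, sub-events everything but events, cuts everything but events and
sub-events; the first 6 s of every clip are censored everywhere.

**Conformity.** A participant's alignment to the group is the Fisher $z$
of the correlation between the log of their step distance vector and the
log of the leave-one-out group median, after trimming five epochs at each
end (`conformity()`, clip-level variant `clip_conformity()`). Logs get an
offset of $10^{-6}\times$ the median positive step value; correlations of
magnitude 1 (possible in degenerate cohorts) are clamped to $1 -
10^{-12}$ and flagged rather than returned as infinite $z$.

**Trait statistics.** Transition rate (transitions per minute,
`transition_rate()`) is summarized across runs with the two-way
random-effects, absolute-agreement, average-measures intraclass
correlation ICC(2,k) (`icc_2k()`), with $F = \mathrm{MSR}/\mathrm{MSE}$
on $(n-1, (n-1)(k-1))$ degrees of freedom and the standard
single-measure confidence bounds stepped up by Spearman-Brown.

**Bootstrap machinery.** `bootstrap_mean()`, `bootstrap_corr()` and
`bootstrap_corr_diff()` share one summary: percentile CI, bootstrap ratio
(BSR = bootstrap mean / bootstrap SE, treated as approximately standard
normal) and the corresponding $p$. Correlations remove outliers
marginally before resampling using a robust z-score
($|x-\mathrm{med}| > 3 \times 1.4826\,\mathrm{MAD}$). The criterion is
sometimes described loosely as three standard deviations about the
median, which is not a standard estimator; a plain-SD-about-the-median
variant is therefore available by flag.

**Surrogates and baselines.** `phase_randomize()` builds null data with
each channel's amplitude spectrum (hence autocorrelation) preserved
exactly and phases drawn independently per channel.
`baseline_representation()` provides the unreduced, PCA and FastICA
embeddings, and `miller_representation()` the sliding-window connectivity
meta-states (44-s windows, FastICA to 5 components, signed-quartile
discretization - sign times within-component quartile rank of the
absolute weight). All of them feed the identical step-distance and
peak-finding code path, since the Mahalanobis form generalizes to any
dimension.

**Conjunction analysis.** Participant-wise transition-minus-meta-stable
volumes are smoothed (6 mm FWHM separable Gaussian), masked at 50% gray
matter probability, and summarized per voxel by a bootstrap ratio
converted to a normal-theory $p$ (`bsr_p_map()`). Maps are thresholded at
$p < 0.001$ with a 250-voxel (1024 mm$^3$ at 1.6 mm isotropic) cluster
extent, and the cross-context conjunction takes the product of two maps
pre-thresholded at 0.05 - so the largest finite conjunction value is
$0.05^2 = 0.0025$, its implied voxelwise threshold (`conjunction_map()`).

## The synthetic cohort generator

Real 7T movie/rest fMRI is access-restricted, so every pipeline stage is
exercised on synthetic cohorts (`simulate_cohort()`) that embody the
attractor picture directly:

* a run draws a sequence of discrete states with shifted-exponential
  dwell times (mean 60 s, 5-sample floor - a "state" shorter than the
  smoothing span is unresolvable and arguably not a meta-state);
* each state has a $K$-dimensional centroid with entries drawn at
  `state_mean_scale` (default 3) noise-SDs;
* the emission is centroid + mean-reverting (Ornstein-Uhlenbeck) drift
  (stationary SD 2, timescale 60 s) + unit white noise.

The drift term deserves a note. It is what produces *worm-like* segments:
consecutive timepoints are each other's nearest neighbors in the
15-dimensional space, so t-SNE renders a dwell as a contiguous curve and
within-state steps are small. Two alternatives fail in instructive ways.
A pure random walk lets long dwells wander as far as neighboring
centroids, planting genuine mid-state reconfigurations; and white noise
alone (no drift) makes all within-state points exchangeable, so the
embedding places consecutive timepoints at arbitrary positions inside a
blob and "tears" appear at data-determined locations that read as
spurious transitions. The same exchangeability argument explains why the
exact zero-variance limit is only clean for distance-faithful
representations (the unreduced baseline), not for t-SNE, whose repulsion
spreads exact duplicates apart.

Movie-like cohorts (`shared = TRUE`) share one state sequence across
participants up to per-participant onset jitter (SD 1 s), and carry
planted features in the same formats the features module consumes: event
boundaries placed 4.5 s (the center of the 3-6 s HRF window) *before*
the neural change, nested sub-events and cuts, a continuous
semantic-change vector, an independent boundary vector with matched rate,
and a head-motion vector unrelated to everything. Rest-like cohorts
(`shared = FALSE`) draw independent sequences whose mean dwell carries a
log-normal participant multiplier (SD 0.4) - the planted transition-rate
trait - and carry only the stimulus-independent vectors.

What the generator does *not* emulate: hemodynamic convolution (features
lead neural change by a fixed lag instead), spatially structured voxel
data, scanner drift and physiological noise spectra, partial-volume or
motion artifacts, state revisitation statistics of real cognition, and
between-network correlation structure within a state. Passing tests
therefore demonstrate that the algorithmic pipeline recovers the
structure it assumes, at realistic sizes and noise levels - not that the
method is valid for any particular real acquisition.

## Numerical choices

* **Exact t-SNE with shared affinities.** Runs here are at most ~1000
  timepoints, where exact $O(T^2)$ gradients are faster than tree
  approximations and free of their error knobs. The input affinities
  depend only on the data and perplexity, so the ensemble computes them
  once per run and shares them across all restarts; only the seeded
  random initialization differs. Optimizer: learning rate 200, early
  exaggeration 12 for the first 100 iterations, momentum 0.5 then 0.8,
  sign-adaptive per-coordinate gains, 350 iterations total - at these
  problem sizes the embedding geometry (and the detected peaks) plateau
  well before 350; the short schedule is what makes 100-repetition
  ensembles routine.
* **Seeds.** Iteration $i$ of run $j$ uses `seed + 100000*(j-1) + i - 1`,
  so one integer reproduces a whole cohort bit-for-bit and restarts are
  independent.
* **Failed repetitions** (collapsed embeddings with singular covariance)
  are dropped with a warning; fewer than two survivors is an error.
* **Peak semantics.** Plateaus resolve to their leftmost sample; widths
  are measured at half prominence with linear interpolation at the
  crossings. An exhaustive $O(T^2)$ oracle pins these semantics in the
  test suite over thousands of random vectors, including tied and sparse
  ones.
* **Percentile CIs** use inverse-ECDF quantiles (type 1), so interval
  endpoints are order statistics of the recorded bootstrap distribution.
* **Cluster connectivity** is 6-neighbor (shared faces) by default with a
  26-neighbor flag; labeling is checked against an independent
  graph-components oracle.
* **Degenerate cases** return flagged finite values rather than errors
  where the downstream analysis can continue: clamped $r = \pm 1$ in
  conformity, infinite BSR mapped to $p = 0$, zero-variance differences
  flagged with undefined $\eta^2$.

## Choices where the published description is open

* Step distances are *squared* Mahalanobis (the results wording), with
  `squared = FALSE` available since the methods wording omits the square.
* $\Sigma$ is the covariance of the embedded points; `cov = "diffs"`
  switches to the covariance of successive differences.
* CI percentiles default to 2.5/97.5 ("95% CI" in the figures) with the
  5/95 variant ("5th and 95th percentile" in the text) one argument away.
* The 3-s censor window is symmetric (boundary bin $\pm$ 1); the HRF
  window $[t-6, t-3]$ is inclusive at both ends; onsets with partially
  out-of-range windows are skipped uniformly.
* Bootstrap CI bounds are converted to $t$ by dividing by the plug-in
  standard error of the original differences before the $\eta^2$
  transform.
* t-SNE initialization is random by default (`init = "pca"` available);
  whether the original analysis used PCA initialization is not stated.
* ICA weights are not standardized before signed-quartile discretization.
* Volumes are smoothed before gray-matter masking.

## Problem sizes used by the tests and the acceptance script

The end-to-end checks run a movie-like cohort of 20 participants
(T = 900 s, K = 15, mean dwell 60 s, centroid scale 3) with 20 embedding
repetitions per run; a rest-like cohort of 30 participants with two runs
each at the same length for trait recovery; and a phase-randomized copy
of the movie cohort for the null comparisons. These sizes are the
package's choice of a desk-scale benchmark: large enough for the group
statistics to stabilize, small enough to run on one CPU in minutes. The
published analyses use 100 repetitions; 20 are enough for stable
detection on the synthetic benchmark because its state separation is
explicit.

## Known limitations

* The detector flags *any* prominent network reconfiguration; nothing
  ties a transition to a thought except the validation logic.
* Transition counts include a roughly constant background of spurious
  detections (a few per 15-minute run on the synthetic benchmark), so
  rate estimates from short runs are noisier than the Poisson count
  alone suggests.
* The $\eta^2$ statistic inherits the usual caveat of converted $t$
  statistics: it measures separation of means across participants, not
  variance explained within a run.
* ICC(2,k) assumes no missing cells; runs must be complete.
* On cohorts whose states have little within-state drift relative to
  noise, t-SNE's duplicate-repulsion behavior inflates within-state
  steps; the unreduced baseline is the appropriate control there.
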