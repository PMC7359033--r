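# metastate

Prior-free detection of brain network meta-state transitions in fMRI
timeseries.

## What problem this solves

Whole-brain activity appears to move through *meta-states*: transiently
stable configurations of large-scale network activation. Switches between
them align with narrative event boundaries during movie-watching and are
candidate markers for the arrival of new thoughts at rest. Existing
detectors need priors — group-aligned stimuli, previously visited states,
or a pre-specified event count — which rules out the setting researchers
care most about: a single resting-state run from a single participant.

`metastate` implements a detector that needs no priors, plus the
validation machinery around it. It is aimed at cognitive-neuroscience
researchers working with network-level fMRI timeseries (e.g. dual
regression of group-ICA maps at TR = 1 s) who want per-participant
transition timings, rates, and group-alignment statistics.

## The method

For a run's smoothed `T x K` network-activation matrix:

1. embed the `T` timepoints into 2-D with t-SNE (perplexity 30);
2. compute the squared Mahalanobis step distance between successive
   embedded points, `d_t = (y_{t+1} - y_t)' S^{-1} (y_{t+1} - y_t)`,
   with `S` the empirical covariance of the embedded points;
3. repeat 1–2 many times (default 100) and average the step distance
   vectors — valid because the Mahalanobis form is invariant to the
   arbitrary affine differences between t-SNE runs;
4. mark **transitions** at peaks of the mean step distance vector with
   prominence ≥ 0.06, and **meta-stable** timepoints at troughs at least
   10 samples wide at half prominence.

Around this core the package provides: dual regression and moving-average
smoothing; movie-feature alignment with a censoring cascade, 3–6 s
HRF-lag sampling and eta-squared statistics; leave-one-out group
conformity (run- and clip-level); transition-rate trait statistics
(ICC(2,k)); bootstrap means/correlations with bootstrap ratios;
phase-randomized surrogates; unreduced/PCA/ICA and sliding-window
connectivity baselines; a voxelwise bootstrap-ratio conjunction analysis;
and a synthetic cohort generator with planted meta-states so the whole
pipeline is testable without any data download.

## Worked example

Simulate a small movie-like cohort with planted meta-states, run the
pipeline, and score detection against the planted truth:

```r
library(metastate)
library(dplyr)

sim <- simulate_cohort(sim_params(n_participants = 4), seed = 1)

sdv <- sim$timeseries |>
  smooth_networks(span_s = 5) |>
  ensemble_step_distance(n_iter = 10, n_boot = 0, seed = 1)

tp <- detect_timepoints(sdv, mpp = 0.06, min_width_samples = 10)

score_cohort(filter(tp, kind == "transition"), sim$truth, tol_s = 3) |>
  summarise(precision = mean(precision), recall = mean(recall))
#> # A tibble: 1 × 2
#>   precision recall
#>       <dbl>  <dbl>
#> 1     0.728      1

conformity(sdv) |> summarise(mean_r = mean(r))
#> # A tibble: 1 × 1
#>   mean_r
#>    <dbl>
#> 1  0.524
```

The first table says that at a 3-s tolerance every planted state change
was found, and ~73% of detections correspond to planted changes — the
remainder are the background of smaller reconfigurations any prominence
detector flags; with the benchmark's 20 embedding repetitions per run the
mean precision rises above 0.8. The conformity value (~0.5) reflects the
shared stimulus-like sequence: each participant's step distance vector
correlates with the leave-one-out group median, as movie runs do and rest
runs do not.

Per-run plots:

```r
one <- filter(sdv, participant_id == "p01")
plot_step_distance(one, filter(tp, participant_id == "p01"))
plot_embedding(embed_timepoints(filter(
  smooth_networks(sim$timeseries, 5), participant_id == "p01"
), seed = 1))
```

A thin command-line front end over the same functions lives at
`inst/cli/metastate` (subcommands `simulate`, `embed`, `detect`,
`calibrate`, `conformity`, `icc`, `surrogate`, `baseline`, `sweep`).

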