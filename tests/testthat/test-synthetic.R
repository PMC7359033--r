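test_that("simulation is bit-identical for a fixed seed", {
  p <- sim_params(n_participants = 2, T_s = 200, mean_dwell_s = 30)
  a <- simulate_cohort(p, seed = 42)
  b <- simulate_cohort(p, seed = 42)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$truth, b$truth)
  expect_identical(a$features, b$features)
  c <- simulate_cohort(p, seed = 43)
  expect_false(identical(a$timeseries, c$timeseries))
})

test_that("infeasible parameters are rejected", {
  expect_error(sim_params(mean_dwell_s = 1000, T_s = 900), "shorter")
  expect_error(sim_params(n_participants = 0), "positive")
  expect_error(sim_params(T_s = "long"), "finite")
})

test_that("in the noiseless limit detections coincide with planted truth", {
  # K small enough that the between-state scatter spans all dimensions:
  # otherwise the Mahalanobis whitening amplifies the vanishing-noise
  # directions and the limit is not informative
  p <- sim_params(
    n_participants = 2, T_s = 400, K = 4, n_states = 12, mean_dwell_s = 40,
    state_mean_scale = 3e6, drift_sd = 1e-7, noise_sd = 1e-6,
    jitter_sd_s = 0
  )
  sim <- simulate_cohort(p, seed = 9)
  # distance-faithful (unreduced) route: within-state steps vanish and the
  # only peaks are the planted changes, so detection is exact
  for (pid in c("p01", "p02")) {
    run <- dplyr::filter(sim$timeseries, participant_id == pid)
    rep <- baseline_representation(run, "none")
    d <- step_distance(rep)
    sdv <- tibble::tibble(t_s = run$time_s[-1], step = d)
    truth <- sim$truth$onset_s[sim$truth$participant_id == pid]
    expect_lt(max(d[!sdv$t_s %in% truth]), 1e-4) # ~0 within states
    sc <- score_detection(find_transitions(sdv), truth, tol_s = 0)
    expect_equal(sc$precision, 1)
    expect_equal(sc$recall, 1)
  }
  # the stochastic t-SNE route still recovers every planted transition
  # (exact duplicates repel into unordered blobs, so precision is not
  # guaranteed in this artificial limit - see the methods vignette)
  sdv <- ensemble_step_distance(sim$timeseries,
    n_iter = 3, n_boot = 0, seed = 2, max_iter = 250
  )
  sc <- score_cohort(find_transitions(sdv), sim$truth, tol_s = 0)
  expect_equal(sc$recall, rep(1, 2))
})

test_that("movie-like truths share the group sequence up to jitter", {
  sim <- simulate_cohort(sim_params(n_participants = 6, T_s = 500), seed = 5)
  by_p <- split(sim$truth$onset_s, sim$truth$participant_id)
  # every pair of participants matches almost fully within 3 s
  for (i in 2:6) {
    n <- min(length(by_p[[1]]), length(by_p[[i]]))
    m <- score_detection(by_p[[i]], by_p[[1]], tol_s = 3)
    expect_gt(m$n_matched / n, 0.8)
  }
})

test_that("rest-like truths overlap across participants only at chance", {
  sim <- simulate_cohort(
    sim_params(n_participants = 8, T_s = 600, shared = FALSE),
    seed = 6
  )
  by_p <- split(sim$truth$onset_s, sim$truth$participant_id)
  overlaps <- c()
  for (i in 1:7) {
    for (j in (i + 1):8) {
      m <- score_detection(by_p[[i]], by_p[[j]], tol_s = 1)
      overlaps <- c(overlaps, m$n_matched / max(1, min(
        length(by_p[[i]]),
        length(by_p[[j]])
      )))
    }
  }
  # expected chance rate: ~3 bins matched per onset out of ~60-bin spacing
  expect_lt(mean(overlaps), 0.25)
})

test_that("planted features precede the group neural onsets by the HRF lag", {
  sim <- simulate_cohort(sim_params(n_participants = 3, T_s = 500), seed = 7)
  ev <- sim$features$time_s[sim$features$feature == "events" &
    sim$features$value == 1]
  # with jitter 1 s, each participant's truths sit ~lag after some event
  lags <- purrr::map_dbl(sim$truth$onset_s, function(t) {
    min(abs(t - 4.5 - ev))
  })
  expect_lt(stats::median(lags), 2)
  # rest-like cohorts still carry null features
  simr <- simulate_cohort(
    sim_params(n_participants = 2, T_s = 300, shared = FALSE),
    seed = 8
  )
  expect_setequal(
    unique(simr$features$feature),
    c("independent_events", "head_motion")
  )
})

test_that("jittered sequences stay consistent (one state per segment)", {
  set.seed(10)
  for (i in 1:50) {
    seqn <- metastate:::draw_sequence(300, 40, 6)
    j <- metastate:::jitter_sequence(seqn, 3, 300)
    expect_equal(length(j$states), length(j$onsets) + 1)
    expect_true(all(diff(j$onsets) > 0))
    expect_true(all(j$onsets >= 2 & j$onsets <= 299))
    # no immediate self-transitions survive from the construction
    expect_true(all(diff(seqn$states) != 0))
  }
})

test_that("detection scoring matches the exhaustive matching oracle", {
  set.seed(11)
  for (i in 1:100) {
    d <- sort(runif(sample(0:8, 1), 0, 60))
    tr <- sort(runif(sample(1:8, 1), 0, 60))
    tol <- runif(1, 0.5, 5)
    got <- score_detection(d, tr, tol_s = tol)
    best <- oracle_max_matching(d, tr, tol)
    expect_equal(got$n_matched, best)
  }
})

test_that("scoring handles the degenerate cases with flags", {
  exact <- score_detection(c(10, 20, 30), c(10, 20, 30))
  expect_equal(exact$precision, 1)
  expect_equal(exact$recall, 1)
  expect_equal(exact$f1, 1)
  none <- score_detection(numeric(0), c(10, 20))
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_true(none$flagged)
  expect_error(score_detection(c(1), c(1), tol_s = -1), "nonnegative")
})

test_that("the timeseries tibble is a valid cohort for the pipeline", {
  sim <- simulate_cohort(sim_params(n_participants = 2, T_s = 150), seed = 12)
  ts <- sim$timeseries
  expect_true(all(c("participant_id", "run_id", "run_type", "time_s") %in% names(ts)))
  expect_equal(length(network_cols(ts)), 15)
  expect_equal(unique(ts$run_type), "synthetic")
  expect_equal(nrow(ts), 2 * 150)
  # truths lie within the run
  expect_true(all(sim$truth$onset_s > 0 & sim$truth$onset_s < 150))
})
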