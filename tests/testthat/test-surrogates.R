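test_that("phase randomization preserves amplitude spectrum and mean exactly", {
  set.seed(1)
  for (n in c(128, 129)) { # even and odd lengths
    x <- as.numeric(arima.sim(list(ar = 0.8), n))
    ts <- network_timeseries(cbind(x, rnorm(n)))
    sur <- phase_randomize(ts, seed = 5)
    for (col in network_cols(ts)) {
      a0 <- Mod(fft(ts[[col]]))
      a1 <- Mod(fft(sur[[col]]))
      expect_lt(max(abs(a1 - a0) / (a0 + 1e-12)), 1e-8)
      expect_equal(mean(sur[[col]]), mean(ts[[col]]), tolerance = 1e-8)
    }
    # but the series itself changed
    expect_false(isTRUE(all.equal(sur[[network_cols(ts)[1]]], x)))
  }
})

test_that("surrogate lag-1 autocorrelation tracks the preserved spectrum", {
  set.seed(2)
  x <- as.numeric(arima.sim(list(ar = 0.9), 600))
  ts <- network_timeseries(cbind(x, x * 0 + rnorm(600)))
  sur <- phase_randomize(ts, seed = 3)
  r_orig <- acf(x, plot = FALSE)$acf[2]
  r_sur <- acf(sur[[network_cols(sur)[1]]], plot = FALSE)$acf[2]
  expect_lt(abs(r_sur - r_orig), 0.1)
})

test_that("phases are drawn independently per channel", {
  set.seed(3)
  x <- rnorm(200)
  ts <- network_timeseries(cbind(x, x)) # identical channels in
  sur <- phase_randomize(ts, seed = 1)
  nc <- network_cols(sur)
  expect_false(isTRUE(all.equal(sur[[nc[1]]], sur[[nc[2]]])))
})

test_that("phase randomization destroys planted state structure", {
  sim <- simulate_cohort(sim_params(n_participants = 1, T_s = 450), seed = 4)
  sur <- phase_randomize(sim$timeseries, seed = 6)
  sdv_real <- ensemble_step_distance(smooth_networks(sim$timeseries, 5),
    n_iter = 5, n_boot = 0, seed = 2
  )
  sdv_sur <- ensemble_step_distance(smooth_networks(sur, 5),
    n_iter = 5, n_boot = 0, seed = 2
  )
  tp_real <- find_transitions(sdv_real)
  tp_sur <- find_transitions(sdv_sur)
  rec_real <- score_cohort(tp_real, sim$truth)$recall
  rec_sur <- score_cohort(tp_sur, sim$truth)$recall
  expect_gt(rec_real, 0.8)
  # chance level depends on how many (spurious) peaks the surrogate emits:
  # compare each recall against a circular-shift null with matched counts
  null_recall <- function(onsets, truth, T_s) {
    vapply(1:100, function(i) {
      set.seed(i)
      shifted <- sort((onsets + runif(1, 20, T_s - 20)) %% T_s)
      score_detection(shifted, truth)$recall
    }, numeric(1))
  }
  truth <- sim$truth$onset_s
  expect_gt(rec_real, quantile(null_recall(tp_real$onset_s, truth, 450), 0.99))
  expect_lte(rec_sur, quantile(null_recall(tp_sur$onset_s, truth, 450), 0.95))
})

test_that("surrogate ensembles are less stable across restarts than real data", {
  sim <- simulate_cohort(sim_params(n_participants = 1, T_s = 450), seed = 7)
  sur <- phase_randomize(sim$timeseries, seed = 8)
  w <- function(ts) {
    sdv <- ensemble_step_distance(smooth_networks(ts, 5),
      n_iter = 8, n_boot = 200, seed = 3
    )
    mean(sdv$ci_high - sdv$ci_low)
  }
  expect_gt(w(sur), w(sim$timeseries))
})

test_that("PCA baseline recovers a planted 2-D subspace", {
  set.seed(5)
  basis <- qr.Q(qr(matrix(rnorm(10 * 2), 10, 2)))
  scores <- matrix(rnorm(300 * 2, sd = c(4, 2)), 300, 2, byrow = TRUE)
  x <- scores %*% t(basis) + matrix(rnorm(3000, sd = 1e-4), 300, 10)
  ts <- network_timeseries(x)
  rep <- baseline_representation(ts, "pca")
  v <- stats::prcomp(x)$rotation[, 1:2]
  # principal angles between recovered and true subspaces are ~0
  ang <- acos(pmin(1, svd(t(v) %*% basis)$d))
  expect_lt(max(ang), 1e-3)
  expect_equal(attr(rep, "method"), "pca")
  expect_named(rep, c("time_s", "dim1", "dim2"))
})

test_that("the unreduced baseline passes the smoothed series through", {
  ts <- make_run(80, 6)
  rep <- baseline_representation(ts, "none")
  expect_equal(unname(as.matrix(rep[, -1])), unname(as_run_matrix_for_test(ts)))
  # and the generalized Mahalanobis step distance accepts K dims
  d <- step_distance(rep)
  expect_length(d, 79)
  expect_true(all(d >= 0))
})

test_that("baseline step distances keep the affine invariance", {
  ts <- make_run(100, 6, seed = 2)
  rep <- baseline_representation(ts, "pca")
  co <- as.matrix(rep[, c("dim1", "dim2")])
  d0 <- step_distance(co)
  set.seed(6)
  a <- matrix(rnorm(4), 2, 2)
  expect_equal(step_distance(co %*% t(a)), d0, tolerance = 1e-8)
})

test_that("FastICA separates independent sources on a toy mixture", {
  set.seed(9)
  s <- cbind(runif(500) - 0.5, rbinom(500, 1, 0.5) - 0.5 + rnorm(500, sd = 0.05))
  x <- s %*% matrix(c(2, 1, 1, 2), 2, 2)
  rec <- metastate:::fast_ica(x, 2, seed = 1)
  expect_true(attr(rec, "converged"))
  cors <- abs(cor(rec, s))
  # each source matches one recovered component up to sign/permutation
  expect_gt(max(cors[, 1]), 0.95)
  expect_gt(max(cors[, 2]), 0.95)
})

test_that("ICA baseline returns two components or errors after retries", {
  ts <- make_run(150, 6, seed = 3)
  rep <- baseline_representation(ts, "ica", seed = 2)
  expect_named(rep, c("time_s", "dim1", "dim2"))
  expect_equal(attr(rep, "method"), "ica")
})

test_that("the sliding-window representation has the stated geometry", {
  ts <- make_run(200, 8, seed = 4)
  rep <- miller_representation(ts, window_s = 44, step_s = 1, n_components = 5, seed = 1)
  expect_equal(nrow(rep), 200 - 44 + 1)
  expect_named(rep, c("t_s", paste0("dim", 1:5)))
  vals <- as.matrix(rep[, -1])
  expect_true(all(vals %in% c(-4:-1, 1:4)))
  expect_true(attr(rep, "discretized"))
  # each component's absolute weights split into 4 quartile bins
  tab <- table(abs(vals[, 1]))
  expect_equal(length(tab), 4L)
})

test_that("two-sample windows are impossible and constant windows error", {
  ts <- make_run(100, 5)
  expect_error(miller_representation(ts, window_s = 2), "impossible")
  ts2 <- ts
  ts2[[network_cols(ts2)[1]]][10:20] <- 3 # constant stretch inside a window
  expect_error(
    miller_representation(ts2, window_s = 10, n_components = 2),
    "constant network in window"
  )
})
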