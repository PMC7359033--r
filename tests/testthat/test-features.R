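test_that("boundary vectors allocate onsets to the nearest 1-s bin", {
  f <- boundary_vector(c(10.4), 20)
  expect_equal(f$time_s[f$value == 1], 10)
  # coincident onsets collapse to one
  f2 <- boundary_vector(c(5.0, 5.3), 20)
  expect_equal(sum(f2$value), 1)
  expect_equal(f2$time_s[f2$value == 1], 5)
  # empty list gives an all-zero vector of full length
  f3 <- boundary_vector(numeric(0), 15)
  expect_equal(sum(f3$value), 0)
  expect_equal(nrow(f3), 15)
  expect_error(boundary_vector(c(25), 20), "within")
})

test_that("change magnitude follows the stated constructions", {
  m <- cbind(c(0, 1, 1), c(0, 0, 2))
  f <- change_magnitude(m, "sum_derivative")
  expect_equal(f$value, c(0, 1, 2))
  # constant matrix: all zeros
  expect_equal(change_magnitude(matrix(2, 5, 3), "sum_derivative")$value, rep(0, 5))
  # audio: absolute derivative with leading zero
  fa <- change_magnitude(cbind(c(1, 0.5, 0.8)), "abs_derivative")
  expect_equal(fa$value, c(0, 0.5, 0.3))
})

test_that("the censoring cascade masks lower levels around higher boundaries", {
  ev <- boundary_vector(10, 40, name = "events")
  sub <- boundary_vector(c(10, 20), 40, name = "sub_events")
  cut <- boundary_vector(c(20, 30), 40, name = "cuts")
  cont <- change_magnitude(matrix(rnorm(80), 40, 2), name = "sem")
  feats <- dplyr::bind_rows(ev, sub, cut, cont)
  out <- censor_cascade(feats,
    hierarchy = c("events", "sub_events", "cuts"),
    clip_starts_s = 0
  )
  cen <- out$censored
  usable_of <- function(name) cen$usable[cen$feature == name]
  # first 6 s of the clip censored everywhere
  for (nm in c("events", "sub_events", "cuts", "sem")) {
    expect_true(all(!usable_of(nm)[1:6]))
  }
  # event at bin 10 masks bins 9-11 in everything below, not in events
  expect_true(all(!usable_of("sub_events")[10:12])) # time_s 9,10,11
  expect_true(all(!usable_of("cuts")[10:12]))
  expect_true(all(!usable_of("sem")[10:12]))
  expect_true(all(usable_of("events")[8:13]))
  # sub-event at 20 masks cuts and sem at 19-21, but not events
  expect_true(all(!usable_of("cuts")[20:22]))
  expect_true(all(usable_of("events")[20:22]))
  # cut at 30 masks only sem
  expect_true(all(!usable_of("sem")[30:32]))
  expect_true(all(usable_of("sub_events")[30:32]))
  # hand count of surviving cut bins: 40 - 6 (clip) - 3 (event@10)
  #   - 3 (sub@20; sub@10 overlaps the event window) = 28
  expect_equal(sum(usable_of("cuts")), 28)
  # uncensored variant only removes the clip-onset bins
  unc <- out$uncensored
  expect_equal(sum(!unc$usable[unc$feature == "sem"]), 6)
})

test_that("censoring is idempotent and order-independent within the hierarchy", {
  set.seed(3)
  feats <- dplyr::bind_rows(
    boundary_vector(c(8, 25), 50, name = "events"),
    boundary_vector(c(8, 15, 33), 50, name = "sub_events"),
    change_magnitude(matrix(rnorm(100), 50, 2), name = "sem")
  )
  once <- censor_cascade(feats, hierarchy = c("events", "sub_events"))$censored
  twice <- censor_cascade(once, hierarchy = c("events", "sub_events"))$censored
  expect_equal(once$usable, twice$usable)
})

test_that("unknown or non-boundary hierarchy names are rejected", {
  feats <- boundary_vector(5, 20, name = "events")
  expect_error(censor_cascade(feats, hierarchy = c("events", "nope")), "not found")
  cont <- change_magnitude(matrix(rnorm(40), 20, 2), name = "sem")
  expect_error(
    censor_cascade(dplyr::bind_rows(feats, cont), hierarchy = c("events", "sem")),
    "boundary"
  )
})

test_that("HRF-lag sampling averages the stated window and skips bad onsets", {
  f <- tibble::tibble(
    feature = "f", kind = "continuous", time_s = 0:29,
    value = 0:29, usable = TRUE
  )
  # onset at 20 s: bins 14,15,16,17
  expect_equal(sample_at_onsets(f, 20), mean(14:17))
  # constant feature returns the constant
  fc <- dplyr::mutate(f, value = 3.3)
  expect_equal(sample_at_onsets(fc, c(10, 20)), 3.3)
  # onset at 4 s: window precedes the run, skipped; grand mean over survivors
  expect_equal(sample_at_onsets(f, c(4, 20)), mean(14:17))
  expect_warning(v <- sample_at_onsets(f, 4), "skipped")
  expect_true(is.na(v))
  # censored bins are excluded from the window average
  f2 <- dplyr::mutate(f, usable = !(time_s %in% c(14, 15)))
  expect_equal(sample_at_onsets(f2, 20), mean(16:17))
})

test_that("eta-squared follows t^2 / (t^2 + df)", {
  # build a cohort where the transition/meta-stable contrast is analytic
  onsets <- purrr::map_dfr(1:6, function(p) {
    tibble::tibble(
      participant_id = sprintf("p%02d", p),
      onset_s = c(20, 40, 60, 80),
      kind = rep(c("transition", "metastable"), 2)
    )
  })
  set.seed(1)
  f <- tibble::tibble(
    feature = "f", kind = "continuous", time_s = 0:99,
    value = rnorm(100), usable = TRUE
  )
  al <- feature_alignment(f, onsets, n_boot = 200, seed = 2)
  # all participants share onsets here, so differences are identical and
  # the result is flagged as degenerate
  expect_true(al$flagged)
  # closed form on non-degenerate numbers
  expect_equal(2^2 / (2^2 + 183), 4 / 187)
  onsets2 <- dplyr::mutate(onsets,
    onset_s = onset_s + rep(seq(0, 10, by = 2), each = 4)
  )
  al2 <- feature_alignment(f, onsets2, n_boot = 200, seed = 2)
  d2 <- purrr::map_dbl(seq(0, 10, by = 2), function(off) {
    sample_at_onsets(f, c(20, 60) + off) - sample_at_onsets(f, c(40, 80) + off)
  })
  t2 <- mean(d2) / (sd(d2) / sqrt(6))
  expect_equal(al2$t, t2)
  expect_equal(al2$df, 5L)
  expect_equal(al2$eta_sq, t2^2 / (t2^2 + 5))
})

test_that("eta-squared is invariant to affine rescaling of the feature", {
  set.seed(8)
  onsets <- purrr::map_dfr(1:5, function(p) {
    tibble::tibble(
      participant_id = sprintf("p%02d", p),
      onset_s = sort(sample(10:90, 6)),
      kind = rep(c("transition", "metastable"), 3)
    )
  })
  f <- tibble::tibble(
    feature = "f", kind = "continuous", time_s = 0:99,
    value = rnorm(100), usable = TRUE
  )
  a <- feature_alignment(f, onsets, n_boot = 100, seed = 1)
  f2 <- dplyr::mutate(f, value = 7 * value + 100)
  b <- feature_alignment(f2, onsets, n_boot = 100, seed = 1)
  expect_equal(a$eta_sq, b$eta_sq, tolerance = 1e-10)
  expect_equal(a$t, b$t, tolerance = 1e-10)
})

test_that("per-network regression gives adjusted R2 of 1 for a copied column", {
  ts <- make_run(100, 5)
  f <- tibble::tibble(
    feature = "f", kind = "continuous", time_s = ts$time_s,
    value = ts[[network_cols(ts)[2]]], usable = TRUE
  )
  out <- suppressWarnings(per_network_feature_regression(ts, f)) # perfect fit
  expect_equal(out$adj_r_squared, 1)
})

test_that("per-network regression is near zero for independent features", {
  set.seed(12)
  vals <- replicate(25, {
    ts <- make_run(300, 5, seed = sample.int(1e6, 1))
    f <- tibble::tibble(
      feature = "f", kind = "continuous", time_s = ts$time_s,
      value = rnorm(300), usable = TRUE
    )
    per_network_feature_regression(ts, f)$adj_r_squared
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("per-network regression rejects undersized or degenerate designs", {
  ts <- make_run(6, 5)
  f <- tibble::tibble(
    feature = "f", kind = "continuous", time_s = ts$time_s,
    value = rnorm(6), usable = TRUE
  )
  expect_error(per_network_feature_regression(ts, f), "few timepoints")
  ts2 <- make_run(50, 4)
  ts2[[network_cols(ts2)[2]]] <- ts2[[network_cols(ts2)[1]]]
  f2 <- tibble::tibble(
    feature = "f", kind = "continuous", time_s = ts2$time_s,
    value = rnorm(50), usable = TRUE
  )
  expect_error(per_network_feature_regression(ts2, f2), "rank deficient")
})
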