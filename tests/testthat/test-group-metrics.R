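# Build a small cohort step tibble from a matrix of step vectors.
sdv_cohort <- function(m) {
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    tibble::tibble(
      participant_id = sprintf("p%02d", j),
      run_id = "r01",
      t_s = seq_len(nrow(m)),
      step = m[, j]
    )
  })
}

test_that("conformity clamps degenerate perfect correlations", {
  set.seed(1)
  base <- abs(rnorm(60, 1))
  # three identical participants: each equals the leave-one-out median
  m <- cbind(base, base, base)
  out <- conformity(sdv_cohort(m))
  expect_true(all(out$clamped))
  expect_equal(out$z, rep(atanh(1 - 1e-12), 3), tolerance = 1e-6)
  expect_true(all(is.finite(out$z)))
})

test_that("independent-noise cohorts have near-zero mean conformity", {
  set.seed(2)
  m <- matrix(abs(rnorm(900 * 30)), 900, 30)
  out <- conformity(sdv_cohort(m))
  expect_lt(abs(mean(out$r)), 0.02)
})

test_that("shared structure raises conformity above independent noise", {
  set.seed(3)
  shared <- abs(rnorm(300, sd = 1)) + 2 * rep(c(0, 1), length.out = 300)
  m_shared <- vapply(1:10, function(i) shared + rnorm(300, sd = 0.5), numeric(300))
  m_indep <- vapply(1:10, function(i) {
    abs(rnorm(300)) + 2 * sample(rep(c(0, 1), length.out = 300))
  }, numeric(300))
  cs <- conformity(sdv_cohort(abs(m_shared)))
  ci <- conformity(sdv_cohort(abs(m_indep)))
  bs <- bootstrap_mean(cs$z, seed = 1)
  bi <- bootstrap_mean(ci$z, seed = 2)
  expect_gt(mean(cs$z), mean(ci$z))
  expect_gt(quantile(bs$boot - bi$boot, 0.025), 0) # difference CI excludes 0
})

test_that("conformity is invariant to positive rescaling of a step vector", {
  set.seed(4)
  m <- matrix(abs(rnorm(200 * 5)) + 0.1, 200, 5)
  a <- conformity(sdv_cohort(m), eps = 1e-9)
  m2 <- m
  m2[, 2] <- 5 * m2[, 2] # log-correlation is shift-invariant in logs
  b <- conformity(sdv_cohort(m2), eps = 1e-9)
  expect_equal(a$r[2], b$r[2], tolerance = 1e-6)
})

test_that("trimming drops the stated epochs and zero variance errors", {
  m <- matrix(1, 14, 3) # constant after trimming
  expect_error(conformity(sdv_cohort(m)), "zero-variance|short")
  set.seed(5)
  m2 <- matrix(abs(rnorm(12 * 3)), 12, 3) # 12 - 10 = 2 points left
  expect_error(conformity(sdv_cohort(m2)), "short")
})

test_that("clip conformity equals run conformity for a whole-run clip", {
  set.seed(6)
  m <- matrix(abs(rnorm(120 * 4)) + 0.05, 120, 4)
  sdv <- sdv_cohort(m)
  clips <- tibble::tibble(clip_id = "c01", start_s = 0, end_s = 200)
  run <- conformity(sdv)
  clip <- clip_conformity(sdv, clips)
  expect_equal(clip$r, run$r)
  expect_equal(clip$scope, rep("clip", 4))
})

test_that("clip conformity matches recomputation on sliced vectors", {
  set.seed(7)
  m <- matrix(abs(rnorm(150 * 4)) + 0.05, 150, 4)
  sdv <- sdv_cohort(m)
  clips <- tibble::tibble(
    clip_id = c("c01", "c02"), start_s = c(0, 76), end_s = c(76, 151)
  )
  out <- clip_conformity(sdv, clips, eps = 1e-8)
  manual <- conformity(dplyr::filter(sdv, t_s >= 76), eps = 1e-8)
  expect_equal(out$r[out$clip_id == "c02"], manual$r)
  # clips shorter than 2*trim + 3 error
  expect_error(
    clip_conformity(sdv, tibble::tibble(clip_id = "x", start_s = 0, end_s = 12)),
    "short"
  )
})

test_that("ICC(2,k) is 1 for identical columns and matches the ANOVA oracle", {
  m <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2), c(1, 5, 9, 2))
  r <- icc_2k(m)
  expect_equal(r$icc, 1)
  # worked 4 x 3 example against the lm/anova decomposition
  set.seed(8)
  m2 <- matrix(rnorm(12, sd = 2), 4, 3) + rep(c(0, 2, 4, 6), 3)
  expect_equal(icc_2k(m2)$icc, oracle_icc_2k(m2), tolerance = 1e-12)
})

test_that("ICC(2,k) equals the ANOVA oracle on random matrices", {
  set.seed(9)
  for (i in 1:40) {
    m <- matrix(rnorm(20), 5, 4) + rnorm(5) # row effects
    r <- icc_2k(m)
    expect_equal(r$icc, oracle_icc_2k(m), tolerance = 1e-10)
    expect_equal(r$df1, 4)
    expect_equal(r$df2, 12)
    expect_lte(r$icc, 1)
  }
})

test_that("ICC of pure noise is near zero on average", {
  # average-measures ICC has a small negative null bias of order k/df2,
  # so the near-zero claim needs a reasonable number of participants
  set.seed(10)
  vals <- replicate(100, icc_2k(matrix(rnorm(120), 30, 4))$icc)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("zero between-participant variance warns as degenerate", {
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3) # pure column effects
  expect_warning(r <- icc_2k(m), "degenerate")
  expect_true(is.finite(r$icc))
})

test_that("ICC F statistic and CI have the expected structure", {
  set.seed(11)
  m <- matrix(rnorm(184 * 4), 184, 4) + 2 * rnorm(184)
  r <- icc_2k(m)
  expect_equal(r$df1, 183)
  expect_equal(r$df2, 549)
  expect_true(r$ci[1] < r$icc && r$icc < r$ci[2])
  expect_lt(r$p, 0.001) # strong row effects
  td <- tidy(r)
  expect_named(td, c("icc", "ci_low", "ci_high", "statistic", "df1", "df2", "p.value"))
})

test_that("clip-wise metric correlations behave at the extremes", {
  set.seed(12)
  cov_tbl <- tibble::tibble(clip_id = sprintf("c%02d", 1:8), value = rnorm(8))
  # metric identical to the covariate for every participant: mean r = 1
  metric <- purrr::map_dfr(1:5, function(p) {
    tibble::tibble(
      participant_id = sprintf("p%02d", p),
      clip_id = cov_tbl$clip_id, value = cov_tbl$value
    )
  })
  b <- clipwise_metric_correlation(metric, cov_tbl, n_boot = 200, seed = 1)
  expect_equal(b$estimate, 1)
  # independent metric: CI contains zero
  metric2 <- dplyr::mutate(metric, value = rnorm(dplyr::n()))
  b2 <- clipwise_metric_correlation(metric2, cov_tbl, n_boot = 200, seed = 2)
  expect_true(b2$ci[1] <= 0 && 0 <= b2$ci[2])
  expect_error(
    clipwise_metric_correlation(metric, dplyr::mutate(cov_tbl, value = 1)),
    "constant"
  )
})
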