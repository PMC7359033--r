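# Small fixtures built in code.

# A single deterministic run as a network timeseries tibble.
make_run <- function(T = 120, K = 5, seed = 1, participant_id = NULL,
                     run_id = NULL) {
  set.seed(seed)
  network_timeseries(matrix(rnorm(T * K), T, K),
    participant_id = participant_id, run_id = run_id
  )
}

# Wrap a numeric vector as a single-run step distance tibble.
make_sdv <- function(x, t0 = 1) {
  tibble::tibble(t_s = seq_along(x) + t0 - 1, step = x)
}

# Two well-separated 15-D Gaussian clusters as one run.
make_two_cluster_run <- function(T = 200, K = 15, sep = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(T * K), T, K)
  x[seq_len(T / 2), 1] <- x[seq_len(T / 2), 1] + sep
  list(ts = network_timeseries(x), labels = rep(1:2, each = T / 2))
}

as_run_matrix_for_test <- function(ts) {
  as.matrix(ts[, network_cols(ts)])
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
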