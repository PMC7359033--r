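# Repeated 2-D embedding of a run and the squared-Mahalanobis step distance
# between successive embedded timepoints, averaged across repetitions.
#
# t-SNE is computed exactly (no Barnes-Hut approximation; runs here are a few
# hundred to ~1000 timepoints). Input affinities depend only on the data and
# the perplexity, so the ensemble computes them once per run and shares them
# across all random restarts.

tsne_init <- function(x, init, seed) {
  withr_seed(seed)
  n <- nrow(x)
  if (init == "pca") {
    pc <- stats::prcomp(x, rank. = 2)$x
    pc <- sweep(pc, 2, apply(pc, 2, stats::sd), "/") * 1e-4
    # small seeded jitter keeps restarts distinct, as with random init
    pc + matrix(stats::rnorm(2 * n, sd = 1e-6), n, 2)
  } else {
    matrix(stats::rnorm(2 * n, sd = 1e-4), n, 2)
  }
}

tsne_embed_matrix <- function(x, perplexity, seed, max_iter, init, eta,
                              exaggeration, exag_iter, affinities = NULL) {
  n <- nrow(x)
  if (n <= 3 * perplexity) {
    stop(sprintf(
      paste0(
        "run has %d timepoints but perplexity %g needs more than %g; ",
        "lower `perplexity` or supply a longer run"
      ),
      n, perplexity, 3 * perplexity
    ), call. = FALSE)
  }
  p <- affinities %||% tsne_affinities_cpp(x, perplexity)
  y0 <- tsne_init(x, init, seed)
  tsne_gradient_cpp(p, y0,
    max_iter = max_iter, eta = eta,
    exaggeration = exaggeration, exag_iter = exag_iter
  )
}

#' Embed one run into two dimensions with t-SNE
#'
#' Reduces the K-network representation of a single run to two dimensions at
#' the given perplexity. The embedding is stochastic; a fixed seed gives
#' identical coordinates on every call. The two output dimensions are
#' unit-free and only their geometry is meaningful, which is why downstream
#' step distances use the Mahalanobis metric (invariant to affine maps of the
#' embedding).
#'
#' @param ts Single-run network timeseries tibble (or a plain T x K matrix).
#' @param perplexity t-SNE perplexity (default 30, a moderate value; the run
#'   must be longer than 3 x perplexity timepoints).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Gradient-descent iterations (default 350, of which the
#'   first 100 run with early exaggeration; embeddings of the few-hundred to
#'   ~1000-timepoint runs this method targets stabilize well before this).
#' @param init `"random"` (default) or `"pca"` initialization.
#' @param eta,exaggeration,exag_iter Standard t-SNE optimizer settings:
#'   learning rate, early-exaggeration factor and its duration.
#' @return A tibble with columns `time_s`, `dim1`, `dim2`.
#' @export
embed_timepoints <- function(ts, perplexity = 30, seed = 1L, max_iter = 350,
                             init = c("random", "pca"), eta = 200,
                             exaggeration = 12, exag_iter = 100) {
  init <- match.arg(init)
  seed <- check_seed(seed)
  if (is.matrix(ts)) {
    x <- ts
    time_s <- seq_len(nrow(x)) - 1
  } else {
    x <- as_run_matrix(ts)
    time_s <- ts$time_s
  }
  y <- tsne_embed_matrix(x, perplexity, seed, max_iter, init, eta,
    exaggeration, exag_iter,
    affinities = NULL
  )
  tibble::tibble(time_s = time_s, dim1 = y[, 1], dim2 = y[, 2])
}

#' Squared Mahalanobis step distance between successive embedded timepoints
#'
#' For embedded coordinates `y_1..y_T`, returns
#' `d_t = (y_{t+1} - y_t)' S^{-1} (y_{t+1} - y_t)` where `S` is the empirical
#' covariance of the T embedded points (`cov = "points"`, the default) or of
#' the successive differences (`cov = "diffs"`). Because the Mahalanobis form
#' absorbs any invertible linear map of the coordinates, step vectors from
#' different t-SNE restarts live on a common scale and can be averaged.
#'
#' @param coords T x D matrix or a tibble with `dim*` columns (D = 2 for
#'   t-SNE; higher-dimensional representations from the baseline embeddings
#'   are accepted unchanged).
#' @param cov Which sample the covariance is computed from.
#' @param squared Return squared distances (default) or their square roots.
#' @return Numeric vector of length T - 1, all values nonnegative.
#' @export
step_distance <- function(coords, cov = c("points", "diffs"), squared = TRUE) {
  cov <- match.arg(cov)
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[, grep("^dim", names(coords), value = TRUE), drop = FALSE])
  }
  if (nrow(coords) < 3) stop("need at least 3 timepoints", call. = FALSE)
  d <- diff(coords)
  s <- switch(cov,
    points = stats::cov(coords),
    diffs = stats::cov(d)
  )
  si <- tryCatch(solve(s), error = function(e) {
    stop("embedding covariance is singular (collinear coordinates)", call. = FALSE)
  })
  out <- rowSums((d %*% si) * d)
  out[out < 0] <- 0 # guard against roundoff
  if (!squared) out <- sqrt(out)
  out
}

#' Mean step distance vector across repeated t-SNE embeddings
#'
#' The core of the transition-detection method: each run is embedded
#' `n_iter` times with different random initializations, the squared
#' Mahalanobis step distance vector is computed for each embedding, and the
#' vectors are averaged elementwise. A percentile bootstrap over the
#' `n_iter` per-iteration values gives a confidence ribbon per timepoint.
#'
#' Iteration `i` of a run uses seed `seed + i - 1`; in a cohort, each run's
#' block of seeds is offset deterministically, so a single `seed` reproduces
#' the whole cohort. Iterations whose embedding collapses (singular
#' covariance) are dropped with a warning; fewer than 2 surviving iterations
#' is an error.
#'
#' @param ts Network timeseries tibble; cohorts (with `participant_id` /
#'   `run_id` columns) are processed run by run.
#' @param n_iter Number of embedding repetitions (default 100, as in the
#'   reference analysis; smaller values are useful for quick looks).
#' @param n_boot Bootstrap resamples for the per-timepoint CI (default 1000;
#'   `0` skips the CI, which detection does not need).
#' @param seed Base integer seed.
#' @param probs CI percentiles, default `c(0.025, 0.975)`; `c(0.05, 0.95)`
#'   gives the 5th/95th variant.
#' @inheritParams embed_timepoints
#' @inheritParams step_distance
#' @return A tibble with one row per step: identifier columns (if present in
#'   the input), `t_s` (time of the later timepoint of the step), `step`
#'   (ensemble mean), and `ci_low`/`ci_high` when `n_boot > 0`.
#' @export
ensemble_step_distance <- function(ts, n_iter = 100, n_boot = 1000, seed = 1L,
                                   probs = c(0.025, 0.975), perplexity = 30,
                                   max_iter = 350, init = c("random", "pca"),
                                   eta = 200, exaggeration = 12,
                                   exag_iter = 100,
                                   cov = c("points", "diffs"), squared = TRUE) {
  init <- match.arg(init)
  cov <- match.arg(cov)
  seed <- check_seed(seed)
  if (n_iter < 2) stop("`n_iter` must be at least 2", call. = FALSE)
  pieces <- split_runs(ts)
  n_failed <- 0L
  out <- purrr::map(seq_along(pieces), function(oi) {
    p <- pieces[[oi]]
    run <- p$data
    x <- as_run_matrix(run)
    base <- run_seed(seed, oi)
    aff <- tsne_affinities_cpp(x, perplexity)
    steps <- purrr::map(seq_len(n_iter), function(i) {
      tryCatch(
        {
          y <- tsne_embed_matrix(x, perplexity, base + i - 1L, max_iter, init,
            eta, exaggeration, exag_iter,
            affinities = aff
          )
          step_distance(y, cov = cov, squared = squared)
        },
        error = function(e) NULL
      )
    })
    failed <- purrr::map_lgl(steps, is.null)
    n_failed <<- n_failed + sum(failed)
    steps <- steps[!failed]
    if (length(steps) < 2) {
      stop("fewer than 2 embedding iterations survived", call. = FALSE)
    }
    m <- do.call(rbind, steps) # iterations x (T-1)
    res <- tibble::tibble(t_s = run$time_s[-1], step = colMeans(m))
    if (n_boot > 0) {
      ci <- step_ci(m, n_boot, base + n_iter, probs)
      res$ci_low <- ci[1, ]
      res$ci_high <- ci[2, ]
    }
    p$result <- res
    p
  })
  if (n_failed > 0) {
    warning(sprintf("%d embedding iteration(s) failed and were excluded", n_failed))
  }
  bind_runs(out)
}

# Percentile bootstrap over iterations: resample iteration indices per
# replicate (jointly across timepoints) and record each replicate's mean
# step vector.
step_ci <- function(m, n_boot, seed, probs) {
  withr_seed(seed)
  n <- nrow(m)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot <- matrix(0, n_boot, ncol(m))
  for (b in seq_len(n_boot)) {
    boot[b, ] <- colMeans(m[idx[b, ], , drop = FALSE])
  }
  apply(boot, 2, stats::quantile, probs = probs, names = FALSE, type = 1)
}
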