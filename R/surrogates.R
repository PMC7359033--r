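# Phase-randomized surrogate data and alternative embedding baselines
# (unreduced, PCA, FastICA, and the sliding-window connectivity meta-state
# representation of Miller and colleagues).

phase_randomize_vec <- function(x) {
  n <- length(x)
  xf <- stats::fft(x)
  half <- (n - 1) %/% 2 # bins with a distinct conjugate partner
  if (half > 0) {
    phi <- stats::runif(half, 0, 2 * pi)
    i <- 2:(half + 1)
    xf[i] <- Mod(xf[i]) * exp(1i * phi)
    xf[n + 2 - i] <- Conj(xf[i])
  }
  # DC (and Nyquist for even n) untouched: mean and spectrum preserved
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Phase-randomized surrogate of a network timeseries
#'
#' Each channel is Fourier transformed, the phases of all non-DC,
#' non-Nyquist bins are replaced by independent uniform draws (conjugate
#' symmetry preserved), and the signal inverse transformed. Each channel's
#' amplitude spectrum - hence autocorrelation - and mean are preserved
#' exactly, while temporal state structure is destroyed. Phases are drawn
#' independently per channel.
#'
#' @param ts Network timeseries tibble (cohorts processed per run) or a
#'   plain numeric matrix with channels in columns.
#' @param seed Integer seed.
#' @return Surrogate data of the same shape and type.
#' @export
phase_randomize <- function(ts, seed = 1L) {
  seed <- check_seed(seed)
  withr_seed(seed)
  if (is.matrix(ts)) {
    if (nrow(ts) < 4) stop("need at least 4 timepoints", call. = FALSE)
    return(apply(ts, 2, phase_randomize_vec))
  }
  pieces <- split_runs(ts)
  out <- purrr::map(pieces, function(p) {
    run <- p$data
    if (nrow(run) < 4) stop("need at least 4 timepoints", call. = FALSE)
    nets <- network_cols(run)
    run[nets] <- purrr::map(run[nets], phase_randomize_vec)
    p$result <- run
    p
  })
  bind_runs(out)
}

# FastICA with the logcosh contrast and symmetric decorrelation. Returns the
# source activations (rows of the input mapped to n_comp components).
fast_ica <- function(x, n_comp, seed = 1L, max_iter = 200, tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)[seq_len(n_comp)]
  if (anyNA(keep)) stop("data rank too low for requested components", call. = FALSE)
  wh <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(eg$values[keep]), n_comp)
  z <- x %*% wh # whitened, n x n_comp
  withr_seed(seed)
  w <- matrix(stats::rnorm(n_comp^2), n_comp)
  sym_orth <- function(w) {
    s <- w %*% t(w)
    e <- eigen(s, symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), n_comp) %*% t(e$vectors)
    solve_sqrt %*% w
  }
  w <- sym_orth(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wx <- z %*% t(w) # n x n_comp sources
    g <- tanh(wx)
    gp <- 1 - g^2
    w_new <- t(g) %*% z / n - diag(colMeans(gp), n_comp) %*% w
    w_new <- sym_orth(w_new)
    delta <- max(abs(1 - abs(diag(w_new %*% t(w))))) # rotation-free change
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(z %*% t(w), unmixing = w, whitening = wh, converged = converged)
}

#' Alternative embedding baselines for the step-distance pipeline
#'
#' Produces the representations the t-SNE embedding is benchmarked against:
#' `"none"` keeps the (smoothed) K-network series itself, `"pca"` and
#' `"ica"` reduce it to 2 linear components. Step distances and peak finding
#' apply to these representations unchanged - the Mahalanobis form
#' generalizes to any dimension.
#'
#' @param ts Single-run network timeseries tibble.
#' @param method `"none"`, `"pca"` or `"ica"`.
#' @param seed Seed for ICA (random unmixing init; non-convergence retries
#'   with fresh seeds before failing).
#' @param n_comp Number of components for pca/ica (default 2).
#' @return Tibble with `time_s` and `dim*` columns; attribute `"method"`.
#' @export
baseline_representation <- function(ts, method = c("none", "pca", "ica"),
                                    seed = 1L, n_comp = 2) {
  method <- match.arg(method)
  x <- as_run_matrix(ts)
  coords <- switch(method,
    none = x,
    pca = stats::prcomp(x)$x[, seq_len(n_comp), drop = FALSE],
    ica = {
      res <- NULL
      for (try in 0:2) {
        res <- fast_ica(x, n_comp, seed = check_seed(seed) + try)
        if (attr(res, "converged")) break
      }
      if (!attr(res, "converged")) stop("FastICA failed to converge", call. = FALSE)
      res
    }
  )
  out <- tibble::as_tibble(as.matrix(coords), .name_repair = "minimal")
  names(out) <- sprintf("dim%d", seq_len(ncol(out)))
  out <- dplyr::bind_cols(tibble::tibble(time_s = ts$time_s), out)
  attr(out, "method") <- method
  out
}

#' Sliding-window connectivity meta-state representation (Miller)
#'
#' The sliding-window baseline: pairwise network correlations in `window_s`
#' windows slid in `step_s` increments, FastICA of the vectorized
#' upper-triangle connectivity patterns to `n_components` weight
#' timeseries, and discretization of each weight to its signed quartile
#' (sign times the within-component quartile rank of the absolute weight,
#' values in ±1..±4).
#'
#' @param ts Single-run network timeseries tibble (typically a richer,
#'   e.g. 50-network, representation).
#' @param window_s Correlation window in seconds (default 44). Windows of 2
#'   samples are impossible: pairwise correlations are then exactly ±1.
#' @param step_s Window increment (default 1).
#' @param n_components ICA components (default 5).
#' @param seed ICA seed.
#' @param discretize Apply the signed-quartile mapping (default TRUE).
#' @return Tibble of `t_s` (window start) and `dim1..dimN`; attributes
#'   `"method" = "miller"` and `"discretized"`.
#' @export
miller_representation <- function(ts, window_s = 44, step_s = 1,
                                  n_components = 5, seed = 1L,
                                  discretize = TRUE) {
  x <- as_run_matrix(ts)
  tr <- infer_tr(ts$time_s)
  w <- round(window_s / tr)
  if (w < 3) {
    stop("window must cover at least 3 samples; a 2-sample window is impossible (correlations are ±1)",
      call. = FALSE
    )
  }
  step <- max(1L, round(step_s / tr))
  starts <- seq(1L, nrow(x) - w + 1L, by = step)
  ut <- upper.tri(matrix(0, ncol(x), ncol(x)))
  conn <- t(vapply(starts, function(s) {
    win <- x[s:(s + w - 1L), , drop = FALSE]
    if (any(apply(win, 2, stats::sd) == 0)) {
      stop(sprintf("constant network in window starting at sample %d", s), call. = FALSE)
    }
    stats::cor(win)[ut]
  }, numeric(sum(ut))))
  src <- fast_ica(conn, n_components, seed = check_seed(seed))
  vals <- as.matrix(src)
  if (discretize) {
    vals <- apply(vals, 2, function(s) {
      q <- stats::quantile(abs(s), c(0.25, 0.5, 0.75), names = FALSE)
      rank <- findInterval(abs(s), q, left.open = TRUE) + 1L
      ifelse(s >= 0, 1, -1) * rank
    })
  }
  out <- tibble::as_tibble(vals, .name_repair = "minimal")
  names(out) <- sprintf("dim%d", seq_len(ncol(out)))
  out <- dplyr::bind_cols(tibble::tibble(t_s = ts$time_s[starts]), out)
  attr(out, "method") <- "miller"
  attr(out, "discretized") <- discretize
  out
}
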