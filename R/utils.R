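# Shared internal helpers.

# Columns of a network-timeseries tibble that are not network activations.
.id_cols <- c("participant_id", "run_id", "run_type", "time_s", "clip_id")

#' Names of the network activation columns of a timeseries tibble
#'
#' A network timeseries is an ordinary tibble with one row per timepoint,
#' a `time_s` column, optional `participant_id` / `run_id` / `run_type`
#' identifier columns, and one column per brain network. Every column that is
#' not one of the identifiers is treated as a network.
#'
#' @param ts A network timeseries tibble.
#' @return Character vector of network column names.
#' @export
network_cols <- function(ts) {
  setdiff(names(ts), .id_cols)
}

# Grouping keys present in a cohort tibble (possibly none for a single run).
run_keys <- function(ts) {
  intersect(c("participant_id", "run_id"), names(ts))
}

# Split a cohort tibble into single runs, preserving key values.
split_runs <- function(ts) {
  keys <- run_keys(ts)
  if (length(keys) == 0) {
    return(list(list(keys = tibble::tibble(.rows = 1), data = ts)))
  }
  grp <- dplyr::group_by(ts, dplyr::across(dplyr::all_of(keys)))
  keys_tbl <- dplyr::group_keys(grp)
  dat <- dplyr::group_split(grp, .keep = FALSE)
  purrr::map(seq_len(nrow(keys_tbl)), function(i) {
    list(keys = keys_tbl[i, , drop = FALSE], data = dat[[i]])
  })
}

# Bind per-run results back with their keys prepended.
bind_runs <- function(pieces) {
  purrr::map_dfr(pieces, function(p) {
    if (ncol(p$keys) == 0 || nrow(p$result) == 0) {
      p$result
    } else {
      dplyr::bind_cols(p$keys[rep(1, nrow(p$result)), , drop = FALSE], p$result)
    }
  })
}

# Sampling interval inferred from the time axis (seconds).
infer_tr <- function(time_s) {
  if (length(time_s) < 2) {
    return(1)
  }
  stats::median(diff(time_s))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
    abs(seed) >= .Machine$integer.max) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

# Deterministic per-run seed offsets: runs are numbered in group order and
# each run gets a disjoint block of iteration seeds.
run_seed <- function(seed, run_ordinal, block = 100000L) {
  s <- as.double(seed) + as.double(block) * (run_ordinal - 1)
  as.integer(s %% (.Machine$integer.max - 1))
}

as_run_matrix <- function(ts) {
  nets <- network_cols(ts)
  if (length(nets) < 1) {
    stop("no network columns found in timeseries", call. = FALSE)
  }
  m <- as.matrix(ts[, nets, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    stop("network columns must be numeric with no missing values", call. = FALSE)
  }
  m
}
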