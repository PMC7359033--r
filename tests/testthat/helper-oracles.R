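# Independent brute-force oracles the implementation is checked against.
# These deliberately use different algorithms/code paths than the package.

# All local maxima (leftmost sample of a plateau), by direct definition.
oracle_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next
    # plateau scan to the right
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (j < n && x[j + 1] < x[i]) out <- c(out, i)
  }
  out
}

# Prominence by definition: on each side, the minimum between the peak and
# the nearest strictly higher sample (or edge); prominence = height minus
# the higher of the two minima.
oracle_prominence <- function(x, p) {
  h <- x[p]
  n <- length(x)
  left_idx <- seq_len(p - 1)
  higher_left <- left_idx[x[left_idx] > h]
  lseg <- if (length(higher_left)) (max(higher_left) + 1):(p - 1) else left_idx
  right_idx <- if (p < n) (p + 1):n else integer(0)
  higher_right <- right_idx[x[right_idx] > h]
  rseg <- if (length(higher_right)) (p + 1):(min(higher_right) - 1) else right_idx
  lmin <- if (length(lseg)) min(x[lseg]) else h
  rmin <- if (length(rseg)) min(x[rseg]) else h
  list(
    prominence = h - max(lmin, rmin),
    left_base = if (length(lseg)) lseg[which.min(x[lseg])] else p,
    right_base = if (length(rseg)) rseg[which.min(x[rseg])] else p
  )
}

# Width at half prominence by linear scan + interpolation from the peak.
oracle_width <- function(x, p, prom, lbase, rbase, rel_height = 0.5) {
  href <- x[p] - rel_height * prom
  li <- p
  while (li > lbase && x[li - 1] > href) li <- li - 1
  left_ip <- if (li > lbase && x[li - 1] < href) {
    (li - 1) + (href - x[li - 1]) / (x[li] - x[li - 1])
  } else if (li > lbase) li - 1 else lbase
  ri <- p
  while (ri < rbase && x[ri + 1] > href) ri <- ri + 1
  right_ip <- if (ri < rbase && x[ri + 1] < href) {
    (ri + 1) - (href - x[ri + 1]) / (x[ri] - x[ri + 1])
  } else if (ri < rbase) ri + 1 else rbase
  right_ip - left_ip
}

# Exhaustive transition detector built on the oracles above.
oracle_transitions <- function(x, mpp) {
  pk <- oracle_local_maxima(x)
  pk[vapply(pk, function(p) oracle_prominence(x, p)$prominence, 1) >= mpp]
}

# Two-way ANOVA mean squares via lm/anova (independent of the direct sums
# used by the implementation).
oracle_icc_2k <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  d <- data.frame(
    y = as.vector(m),
    row = factor(rep(seq_len(n), k)),
    col = factor(rep(seq_len(k), each = n))
  )
  a <- stats::anova(stats::lm(y ~ row + col, data = d))
  msr <- a["row", "Mean Sq"]
  msc <- a["col", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# Maximum one-to-one matching within tolerance by exhaustive recursion.
oracle_max_matching <- function(d, tr, tol) {
  if (length(d) == 0 || length(tr) == 0) {
    return(0L)
  }
  best <- oracle_max_matching(d[-1], tr, tol) # skip d[1]
  for (i in seq_along(tr)) {
    if (abs(d[1] - tr[i]) <= tol) {
      best <- max(best, 1L + oracle_max_matching(d[-1], tr[-i], tol))
    }
  }
  best
}

# Connected components by graph construction (igraph), 6- or 26-connectivity.
oracle_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) {
    return(list(n = 0L, sizes = integer(0), membership = array(0L, d)))
  }
  pos <- arrayInd(idx, d)
  key <- function(m) m[, 1] + d[1] * (m[, 2] - 1) + d[1] * d[2] * (m[, 3] - 1)
  lookup <- stats::setNames(seq_along(idx), key(pos))
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(g == 0) != 3, , drop = FALSE] # duplicate edges are harmless
  }
  edges <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    j <- lookup[as.character(key(nb[ok, , drop = FALSE]))]
    keep <- !is.na(j)
    edges <- c(edges, rbind(which(ok)[keep], j[keep]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  membership <- array(0L, d)
  membership[idx] <- comp$membership
  list(n = comp$no, sizes = as.integer(comp$csize), membership = membership)
}
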