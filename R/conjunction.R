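# Voxelwise transition-vs-meta-stable contrasts: onset-averaged volumes,
# Gaussian smoothing, bootstrap-ratio p maps, cluster-extent thresholding,
# and the conjunction across task contexts. Volumes are plain 3-D arrays
# (4-D with time last for series); NIfTI I/O via RNifti.

#' Average functional volumes at a set of onsets
#'
#' @param volumes 4-D array (x, y, z, t) of functional volumes.
#' @param onsets_s Onset times in seconds (nonempty, within the run). No HRF
#'   correction is applied: contrast and dependent volumes share the delay.
#' @param tr_s Sampling interval (default 1).
#' @return 3-D array, the voxelwise mean over onset volumes.
#' @export
onset_average_volume <- function(volumes, onsets_s, tr_s = 1) {
  stopifnot(length(dim(volumes)) == 4)
  if (length(onsets_s) == 0) stop("`onsets_s` must be nonempty", call. = FALSE)
  idx <- round(onsets_s / tr_s) + 1L
  if (any(idx < 1 | idx > dim(volumes)[4])) {
    stop("onsets outside the run", call. = FALSE)
  }
  out <- volumes[, , , idx[1], drop = FALSE]
  dim(out) <- dim(volumes)[1:3]
  if (length(idx) > 1) {
    out[] <- 0
    for (i in idx) out <- out + volumes[, , , i]
    out <- out / length(idx)
  }
  out
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve along one axis by banded-matrix multiplication (zero padding).
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  cm <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    cm[cbind(i[ok], j[ok])] <- kernel[o + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- cm %*% matrix(a, nrow = n)
  dim(a) <- da
  aperm(a, order(perm))
}

#' Spatially smooth a volume with a Gaussian kernel
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in
#' voxel units; zero padding at the borders, so total intensity is conserved
#' away from the edges.
#'
#' @param v 3-D array.
#' @param fwhm_mm Full width at half maximum in mm (default 6).
#' @param voxel_size_mm Voxel edge lengths in mm (length 3; default 1.6 mm
#'   isotropic, the native resolution of the targeted acquisitions).
#' @return Smoothed 3-D array.
#' @export
gaussian_smooth_volume <- function(v, fwhm_mm = 6, voxel_size_mm = c(1.6, 1.6, 1.6)) {
  stopifnot(length(dim(v)) == 3)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    v <- conv_axis(v, gauss_kernel(sigma / voxel_size_mm[axis]), axis)
  }
  v
}

#' Voxelwise bootstrap-ratio p map of participant difference volumes
#'
#' Within a gray-matter mask (voxels with at least 50% gray-matter
#' probability), the participant-wise difference volumes are summarized per
#' voxel by a bootstrap over participants: the bootstrap ratio (bootstrap
#' mean / bootstrap SE) approximates a z statistic and is converted to a p
#' value through the normal CDF. Participants are resampled jointly across
#' voxels. Out-of-mask voxels carry the `Inf` sentinel.
#'
#' @param diff_maps List of 3-D arrays, one difference volume (transition
#'   minus meta-stable average) per participant; at least 3.
#' @param gm_mask_prob 3-D array of gray-matter probabilities (same
#'   geometry), or a logical mask.
#' @param n_boot,seed Bootstrap settings.
#' @param two_sided Two-sided p values (default; both signs of effect are
#'   reported).
#' @return 3-D array of p values (in-mask), `Inf` elsewhere; the BSR map is
#'   attached as attribute `"bsr"`.
#' @export
bsr_p_map <- function(diff_maps, gm_mask_prob, n_boot = 1000, seed = 1L,
                      two_sided = TRUE) {
  stopifnot(is.list(diff_maps), length(diff_maps) >= 3)
  d <- dim(diff_maps[[1]])
  mask <- if (is.logical(gm_mask_prob)) gm_mask_prob else gm_mask_prob >= 0.5
  if (!identical(dim(mask), d)) stop("mask geometry mismatch", call. = FALSE)
  if (!any(mask)) stop("gray-matter mask is empty", call. = FALSE)
  x <- vapply(diff_maps, function(v) v[mask], numeric(sum(mask))) # V x P
  n <- ncol(x)
  withr_seed(check_seed(seed))
  counts <- matrix(0, n, n_boot)
  for (b in seq_len(n_boot)) {
    tb <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    counts[, b] <- tb
  }
  bm <- (x %*% counts) / n # V x n_boot bootstrap means
  mu <- rowMeans(bm)
  s <- sqrt(rowSums((bm - mu)^2) / (n_boot - 1))
  bsr <- ifelse(s == 0, ifelse(mu == 0, 0, sign(mu) * Inf), mu / s)
  p_in <- ifelse(is.infinite(bsr), 0,
    (if (two_sided) 2 else 1) * stats::pnorm(-abs(bsr))
  )
  p <- array(Inf, d)
  p[mask] <- p_in
  bsr_map <- array(NA_real_, d)
  bsr_map[mask] <- bsr
  attr(p, "bsr") <- bsr_map
  p
}

# Flood-fill connected-component labeling of a logical 3-D array.
# connectivity 6 = faces only, 26 = faces + edges + corners.
label_components <- function(mask, connectivity = 6) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 26))
  d <- dim(mask)
  offsets <- if (connectivity == 6) {
    rbind(
      c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
      c(0, 1, 0), c(0, 0, -1), c(0, 0, 1)
    )
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(g == 0) != 3, , drop = FALSE]
  }
  labels <- array(0L, d)
  cur <- 0L
  todo <- which(mask)
  for (v in todo) {
    if (labels[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    labels[v] <- cur
    while (length(queue) > 0) {
      idx <- arrayInd(queue, d)
      nbr <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(o) {
        sweep(idx, 2, offsets[o, ], "+")
      }))
      ok <- nbr[, 1] >= 1 & nbr[, 1] <= d[1] &
        nbr[, 2] >= 1 & nbr[, 2] <= d[2] &
        nbr[, 3] >= 1 & nbr[, 3] <= d[3]
      nbr <- nbr[ok, , drop = FALSE]
      lin <- nbr[, 1] + d[1] * (nbr[, 2] - 1L) + d[1] * d[2] * (nbr[, 3] - 1L)
      lin <- unique(lin[mask[lin] & labels[lin] == 0L])
      labels[lin] <- cur
      queue <- lin
    }
  }
  labels
}

#' Threshold a p map and suppress small clusters
#'
#' Voxels with `p < p_thresh` are kept only if they belong to a connected
#' component (6-connectivity by default, i.e. shared faces) of at least
#' `min_extent_voxels` voxels.
#'
#' @param p_map 3-D array of p values (`Inf` allowed as out-of-mask
#'   sentinel).
#' @param p_thresh Voxelwise threshold (default 0.001).
#' @param min_extent_voxels Minimum cluster extent (default 250 voxels;
#'   1024 mm^3 at 1.6 mm isotropic voxels, see [cluster_extent_mm3()]).
#' @param connectivity 6 (faces, default) or 26.
#' @return Logical 3-D array, the surviving-voxel mask; cluster labels of
#'   survivors attached as attribute `"labels"`.
#' @export
threshold_and_cluster <- function(p_map, p_thresh = 0.001,
                                  min_extent_voxels = 250, connectivity = 6) {
  supra <- is.finite(p_map) & p_map < p_thresh
  labels <- label_components(supra, connectivity)
  sizes <- tabulate(labels[labels > 0])
  keep_ids <- which(sizes >= min_extent_voxels)
  mask <- array(labels %in% keep_ids & supra, dim(p_map))
  attr(mask, "labels") <- array(ifelse(mask, labels, 0L), dim(p_map))
  mask
}

#' Conjunction of two p maps across task contexts
#'
#' Both maps are thresholded at `pre_thresh` (default 0.05) with
#' above-threshold voxels set to infinity, and the voxelwise product taken;
#' a finite conjunction value therefore requires both contexts to pass, and
#' the largest finite value is `pre_thresh^2` (0.0025 at the default) - the
#' implied voxelwise threshold of the conjunction. Finite voxels are then
#' cluster-extent filtered.
#'
#' @param p_a,p_b 3-D p maps with identical geometry.
#' @param pre_thresh Per-map threshold before the product (default 0.05).
#' @inheritParams threshold_and_cluster
#' @return 3-D array of conjunction p values, `Inf` at suppressed voxels.
#' @export
conjunction_map <- function(p_a, p_b, pre_thresh = 0.05,
                            min_extent_voxels = 250, connectivity = 6) {
  if (!identical(dim(p_a), dim(p_b))) stop("geometry mismatch", call. = FALSE)
  pa <- ifelse(is.finite(p_a) & p_a < pre_thresh, p_a, Inf)
  pb <- ifelse(is.finite(p_b) & p_b < pre_thresh, p_b, Inf)
  conj <- pa * pb
  keep <- threshold_and_cluster(conj,
    p_thresh = Inf,
    min_extent_voxels = min_extent_voxels, connectivity = connectivity
  )
  conj[!keep] <- Inf
  conj
}

#' Implied voxelwise threshold of a conjunction
#'
#' @param pre_thresh Per-map threshold (default 0.05).
#' @return `pre_thresh^2`, the largest finite conjunction p value.
#' @export
conjunction_implied_threshold <- function(pre_thresh = 0.05) {
  pre_thresh^2
}

#' Cluster extent in cubic millimetres
#'
#' @param min_extent_voxels Cluster extent in voxels (default 250).
#' @param voxel_size_mm Voxel edge lengths in mm (default 1.6 isotropic).
#' @return Extent volume in mm^3 (1024 at the defaults).
#' @export
cluster_extent_mm3 <- function(min_extent_voxels = 250,
                               voxel_size_mm = c(1.6, 1.6, 1.6)) {
  min_extent_voxels * prod(voxel_size_mm)
}
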