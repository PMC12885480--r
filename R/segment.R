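#' Marker-channel intensity stack
#'
#' A co-registered 3D intensity image of an anatomical marker (cytosolic or
#' nuclear), used to build region masks for FLIM fitting.
#'
#' @param intensity 3D nonnegative numeric array `(z, y, x)`.
#' @param voxel_size Numeric `(z, y, x)` voxel size in micrometres.
#' @param marker_kind `"cytosolic"` or `"nuclear"`.
#' @return An object of class `marker_stack`.
#' @export
marker_stack <- function(intensity, voxel_size = c(2, 0.4, 0.4),
                         marker_kind = c("cytosolic", "nuclear")) {
  if (length(dim(intensity)) != 3L) stopf("intensity must be a 3D array")
  if (any(!is.finite(intensity))) stopf("intensity must be finite")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("voxel_size must be three positive values (z, y, x)")
  structure(list(intensity = intensity, voxel_size = as.numeric(voxel_size),
                 marker_kind = match.arg(marker_kind)),
            class = "marker_stack")
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a volume with an anisotropic Gaussian whose standard deviation is
#' given in micrometres and converted to voxels per axis, so the physical blur
#' is isotropic despite anisotropic sampling. Borders are handled by
#' reflection.
#'
#' @param vol 3D numeric array `(z, y, x)`.
#' @param sigma_um Standard deviation in micrometres (scalar).
#' @param voxel_size `(z, y, x)` voxel size in micrometres.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(vol, sigma_um, voxel_size) {
  if (sigma_um < 0) stopf("sigma_um must be >= 0")
  if (sigma_um == 0) return(vol)
  out <- vol
  for (axis in 1:3) {
    s <- sigma_um / voxel_size[axis]
    if (s < 1e-3) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    out <- .conv_axis(out, k, axis)
  }
  out
}

# 1D convolution along one axis of a 3D array with reflect padding
.conv_axis <- function(vol, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(vol)[axis]
  # reflected index sequence of length n + 2r
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  if (r > n) {  # tiny axes: clamp-pad the remainder
    idx <- c(rep(1L, r - n), idx, rep(n, r - n))
  }
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  d <- dim(v)
  m <- matrix(v[idx, , ], nrow = length(idx))
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * m[(j - 1L) + seq_len(n), , drop = FALSE]
  v <- array(out, d)
  aperm(v, order(perm))
}

#' Histogram-based global thresholds
#'
#' `threshold_otsu()` maximises the between-class variance over a 256-bin
#' histogram. `threshold_multiotsu()` generalises to `k` classes by exhaustive
#' search over threshold pairs (only `k = 3` is supported) and returns the
#' thresholds in increasing order. `threshold_li()` iterates Li's minimum
#' cross-entropy fixed point.
#'
#' @param x Numeric values (the image intensities).
#' @param n_bins Histogram resolution.
#' @param k Number of classes for the multi-level variant.
#' @return A threshold (or increasing vector of `k - 1` thresholds); values
#'   strictly above the threshold are foreground.
#' @name thresholds
NULL

.hist256 <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NULL)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  cnt <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L),
                       n_bins), n_bins)
  list(mids = mids, counts = cnt)
}

#' @rdname thresholds
#' @export
threshold_otsu <- function(x, n_bins = 256L) {
  h <- .hist256(x, n_bins)
  if (is.null(h)) return(max(x))
  w <- h$counts / sum(h$counts)
  mu <- cumsum(w * h$mids)
  om <- cumsum(w)
  mu_t <- mu[length(mu)]
  valid <- om > 0 & om < 1
  bc <- (mu_t * om - mu)^2 / (om * (1 - om))
  bc[!valid] <- -Inf
  h$mids[which.max(bc)]
}

#' @rdname thresholds
#' @export
threshold_multiotsu <- function(x, k = 3L, n_bins = 256L) {
  if (k != 3L) stopf("only k = 3 classes are supported")
  h <- .hist256(x, n_bins)
  if (is.null(h)) return(rep(max(x), 2))
  w <- h$counts / sum(h$counts)
  cw <- c(0, cumsum(w))
  cm <- c(0, cumsum(w * h$mids))
  # class statistic between breakpoints (i, j]: weight and mean
  best <- -Inf; best_ij <- c(1L, 2L)
  for (i in seq_len(n_bins - 2L)) {
    w1 <- cw[i + 1]; m1s <- cm[i + 1]
    if (w1 <= 0) next
    for (j in (i + 1L):(n_bins - 1L)) {
      w2 <- cw[j + 1] - cw[i + 1]
      w3 <- 1 - cw[j + 1]
      if (w2 <= 0 || w3 <= 0) next
      m2s <- cm[j + 1] - cm[i + 1]
      m3s <- cm[n_bins + 1] - cm[j + 1]
      v <- m1s^2 / w1 + m2s^2 / w2 + m3s^2 / w3
      if (v > best) { best <- v; best_ij <- c(i, j) }
    }
  }
  h$mids[best_ij]
}

#' @rdname thresholds
#' @export
threshold_li <- function(x, n_bins = 256L) {
  lo <- min(x)
  if (max(x) <= lo) return(lo)
  # offset so all values are positive (log of class means must exist)
  off <- lo - 1e-8 * (max(x) - lo) - .Machine$double.eps
  y <- x - off
  t_cur <- mean(y)
  tol <- 1e-6 * (max(y) - min(y))
  for (it in seq_len(200L)) {
    m_back <- mean(y[y <= t_cur])
    m_fore <- mean(y[y > t_cur])
    if (!is.finite(m_back) || !is.finite(m_fore)) break
    t_new <- (m_back - m_fore) / (log(m_back) - log(m_fore))
    if (!is.finite(t_new) || abs(t_new - t_cur) < tol) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur + off
}

#' Connected-component labelling in 3D
#'
#' Labels foreground voxels using 26-connectivity (face, edge and corner
#' neighbours).
#'
#' @param mask 3D logical array.
#' @return Integer array of the same shape; 0 is background, components are
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  fg <- which(mask)
  if (!length(fg)) return(lab)
  comp <- 0L
  sizes <- integer(0)
  for (start in fg) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    size <- 0L
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      size <- size + length(cur)
      cz <- ((cur - 1L) %% nz) + 1L
      cy <- (((cur - 1L) %/% nz) %% ny) + 1L
      cx <- ((cur - 1L) %/% (nz * ny)) + 1L
      for (r in seq_len(nrow(offs))) {
        z <- cz + offs[r, 1]; y <- cy + offs[r, 2]; x <- cx + offs[r, 3]
        ok <- z >= 1 & z <= nz & y >= 1 & y <= ny & x >= 1 & x <= nx
        if (!any(ok)) next
        nb <- (x[ok] - 1L) * nz * ny + (y[ok] - 1L) * nz + z[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- comp
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
    sizes <- c(sizes, size)
  }
  # renumber by decreasing size
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(comp)
  relab[ord] <- seq_len(comp)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Keep the largest connected component
#'
#' @param mask 3D logical array.
#' @return Logical mask of the largest 26-connected component.
#' @export
largest_component <- function(mask) {
  label_components(mask) == 1L
}

#' Segmentation recipe
#'
#' Describes a smoothing + thresholding pipeline for turning a marker channel
#' into a region mask.
#'
#' @param smooth_sigma_um Gaussian smoothing standard deviation in
#'   micrometres.
#' @param method One of `"li"`, `"otsu"`, `"multi_otsu"` (3 classes; voxels
#'   above the highest threshold are kept) or `"two_step_li"` (Li, then a
#'   minimum-volume filter, then Li again within the surviving foreground —
#'   the nuclear-marker recipe).
#' @param keep_largest_component Keep only the largest 26-connected volume.
#' @param min_volume_um3 Minimum component volume in cubic micrometres
#'   (used by `two_step_li`).
#' @param k Number of classes for `multi_otsu`.
#' @return An object of class `seg_recipe`.
#' @export
segmentation_recipe <- function(smooth_sigma_um = 2,
                                method = c("li", "otsu", "multi_otsu",
                                           "two_step_li"),
                                keep_largest_component = FALSE,
                                min_volume_um3 = 1, k = 3L) {
  if (smooth_sigma_um < 0) stopf("smooth_sigma_um must be >= 0")
  structure(list(smooth_sigma_um = smooth_sigma_um,
                 method = match.arg(method),
                 keep_largest_component = keep_largest_component,
                 min_volume_um3 = min_volume_um3, k = as.integer(k)),
            class = "seg_recipe")
}

#' Named segmentation presets
#'
#' The recipes used for the different acquisition types:
#' * `whole_brain_region` — sigma 4 um, Li (whole-brain region extraction);
#' * `mb_cytosolic` — sigma 2 um, Li, largest component (cytosolic marker of
#'   the full mushroom body);
#' * `nuclear_subtype` — two-step Li, sigma 0.5 um, 1 um^3 minimum volume
#'   (subtype-specific nuclear markers);
#' * `somata_mask` — sigma 3 um, 3-class multi-Otsu, highest class;
#' * `calyx_mask` — sigma 5 um, 3-class multi-Otsu, highest class.
#'
#' @param name Preset name.
#' @return A [segmentation_recipe()].
#' @export
segmentation_preset <- function(name = c("whole_brain_region", "mb_cytosolic",
                                         "nuclear_subtype", "somata_mask",
                                         "calyx_mask")) {
  switch(match.arg(name),
    whole_brain_region = segmentation_recipe(4, "li"),
    mb_cytosolic = segmentation_recipe(2, "li", keep_largest_component = TRUE),
    nuclear_subtype = segmentation_recipe(0.5, "two_step_li",
                                          min_volume_um3 = 1),
    somata_mask = segmentation_recipe(3, "multi_otsu"),
    calyx_mask = segmentation_recipe(5, "multi_otsu"))
}

#' Segment a marker channel into a region mask
#'
#' Applies Gaussian smoothing (sigma converted from micrometres to voxels per
#' axis), the recipe's thresholding method, then optional largest-component
#' and minimum-volume filtering. For `two_step_li`, a second Li threshold is
#' computed within the surviving foreground voxels.
#'
#' @param stack A [marker_stack()].
#' @param recipe A [segmentation_recipe()] or preset name.
#' @return 3D logical mask. An empty foreground yields an all-`FALSE` mask
#'   with a warning, never an error.
#' @export
segment_marker <- function(stack, recipe = segmentation_preset("mb_cytosolic")) {
  stopifnot(inherits(stack, "marker_stack"))
  if (is.character(recipe)) recipe <- segmentation_preset(recipe)
  sm <- gaussian_smooth(stack$intensity, recipe$smooth_sigma_um,
                        stack$voxel_size)
  vals <- as.numeric(sm)
  if (max(vals) <= min(vals)) {
    warnf("constant marker image: empty mask returned")
    return(array(FALSE, dim(stack$intensity)))
  }
  mask <- switch(recipe$method,
    li = sm > threshold_li(vals),
    otsu = sm > threshold_otsu(vals),
    multi_otsu = sm > max(threshold_multiotsu(vals, recipe$k)),
    two_step_li = {
      m1 <- sm > threshold_li(vals)
      m1 <- drop_small_components(m1, recipe$min_volume_um3, stack$voxel_size)
      if (any(m1)) m1 & (sm > threshold_li(as.numeric(sm[m1]))) else m1
    })
  dim(mask) <- dim(stack$intensity)
  if (recipe$keep_largest_component && any(mask))
    mask <- largest_component(mask)
  if (!any(mask)) warnf("segmentation produced an empty mask")
  mask
}

# remove connected components smaller than min_volume_um3
drop_small_components <- function(mask, min_volume_um3, voxel_size) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  vx <- prod(voxel_size)
  keep <- which(tabulate(lab[lab > 0L]) * vx > min_volume_um3)
  array(lab %in% keep, dim(mask))
}

#' Match an image to a reference intensity histogram
#'
#' Standard histogram specification: a monotone intensity mapping is built so
#' that the output's empirical CDF matches the reference CDF. Used to
#' normalise marker images against a dataset-average histogram before
#' template work.
#'
#' @param stack A [marker_stack()].
#' @param reference Either a numeric vector of reference intensities or a
#'   list with `mids` and `counts` describing a histogram.
#' @return A [marker_stack()] with remapped intensities.
#' @export
match_reference_histogram <- function(stack, reference) {
  stopifnot(inherits(stack, "marker_stack"))
  x <- as.numeric(stack$intensity)
  if (max(x) <= min(x)) {
    warnf("constant-intensity input: returned unchanged")
    return(stack)
  }
  if (is.list(reference)) {
    if (!all(c("mids", "counts") %in% names(reference)) ||
        sum(reference$counts) <= 0)
      stopf("reference histogram must have nonempty mids and counts")
    # binned reference: linear interpolation of the inverse CDF
    ref_q <- reference$mids
    ref_p <- cumsum(reference$counts) / sum(reference$counts)
    p <- rank(x, ties.method = "max") / length(x)
    y <- approx(ref_p, ref_q, xout = p, rule = 2, ties = "ordered")$y
  } else {
    if (!length(reference)) stopf("reference must be nonempty")
    # sample reference: step inverse CDF (type-1 quantile), so matching an
    # image against its own values is the exact identity
    ref_q <- sort(as.numeric(reference))
    ref_p <- seq_along(ref_q) / length(ref_q)
    p <- rank(x, ties.method = "max") / length(x)
    y <- ref_q[pmax(1L, ceiling(p * length(ref_q)))]
  }
  out <- stack
  out$intensity <- array(y, dim(stack$intensity))
  out
}
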