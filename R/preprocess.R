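#' 4D FLIM photon-count stack
#'
#' Container for a time-resolved 3D image: a nonnegative integer array in
#' `TZYX` order (time bins, then Z, Y, X) together with its acquisition grid
#' and voxel size.
#'
#' @param counts 4D nonnegative array `(time, z, y, x)`; the time extent must
#'   equal `config$n_bins`.
#' @param config A [flim_acquisition()].
#' @param voxel_size Numeric `(z, y, x)` voxel size in micrometres.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(counts, config = flim_acquisition(),
                       voxel_size = c(2, 0.4, 0.4)) {
  if (length(dim(counts)) != 4L) stopf("counts must be a 4D (t, z, y, x) array")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (dim(counts)[1] != config$n_bins)
    stopf("time dimension (%d) must equal config$n_bins (%d)",
          dim(counts)[1], config$n_bins)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("voxel_size must be three positive values (z, y, x)")
  structure(list(counts = counts, config = config,
                 voxel_size = as.numeric(voxel_size)),
            class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("flim_stack: %d time bins, %d x %d x %d voxels (Z Y X), %.2g Mphotons\n",
              d[1], d[2], d[3], d[4], sum(x$counts) / 1e6))
  invisible(x)
}

#' Per-voxel photon totals
#'
#' @param stack A [flim_stack()].
#' @return 3D array `(z, y, x)` of total counts per voxel.
#' @export
voxel_totals <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  apply(stack$counts, c(2, 3, 4), sum)
}

#' Disk-shaped spatial binning kernel
#'
#' The default binning neighbourhood: a 5 x 5 x 1 voxel block in X-Y with the
#' four corner voxels excluded, giving 21 offsets (including the centre). The
#' kernel is flat in Z, reflecting the coarse axial step of the acquisitions.
#'
#' @return Integer matrix with columns `dz`, `dy`, `dx`, one row per offset.
#' @examples
#' nrow(disk_kernel())  # 21
#' @export
disk_kernel <- function() {
  g <- expand.grid(dz = 0L, dy = -2:2, dx = -2:2)
  g <- g[!(abs(g$dy) == 2L & abs(g$dx) == 2L), ]
  as.matrix(g[, c("dz", "dy", "dx")])
}

#' Exclude abnormally bright voxels
#'
#' Voxels whose total photon count strictly exceeds `Q3 + 3 IQR` of the
#' in-mask count distribution are removed from the mask. Such voxels are
#' non-biological artifacts (tracheae, objects caught by imperfect
#' segmentation) and would otherwise be smeared into their neighbours by
#' spatial binning, so this filter runs before [spatial_bin()]. Quartiles use
#' linear interpolation of order statistics (type 7).
#'
#' @param stack A [flim_stack()].
#' @param mask 3D logical array.
#' @param multiplier IQR multiplier above the upper quartile.
#' @return The filtered logical mask.
#' @export
exclude_bright_outliers <- function(stack, mask, multiplier = 3) {
  totals <- voxel_totals(stack)
  if (!identical(dim(totals), dim(mask))) stopf("mask dimensions must match stack")
  vals <- totals[mask]
  if (length(vals) < 4L) {
    warnf("fewer than 4 in-mask voxels: outlier exclusion skipped")
    return(mask)
  }
  q <- quantile(vals, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- q[2] + multiplier * (q[2] - q[1])
  mask & !(totals > thr)
}

#' Spatial binning of decay histograms
#'
#' Sums, for every in-mask voxel, the decay histograms of its in-mask
#' neighbours at the kernel offsets. Out-of-mask and out-of-bounds neighbours
#' contribute nothing (truncated kernel, no renormalisation): binned totals
#' near borders are smaller and handled by the subsequent count filter.
#' Out-of-mask voxels are zeroed in the output.
#'
#' @param stack A [flim_stack()].
#' @param mask 3D logical array.
#' @param kernel Offset matrix as from [disk_kernel()].
#' @return A new [flim_stack()] of binned counts.
#' @export
spatial_bin <- function(stack, mask, kernel = disk_kernel()) {
  stopifnot(inherits(stack, "flim_stack"))
  dims <- dim(stack$counts)
  if (!identical(dims[-1], dim(mask))) stopf("mask dimensions must match stack")
  nz <- dims[2]; ny <- dims[3]; nx <- dims[4]
  src <- stack$counts
  # zero out-of-mask sources so they never contribute
  src <- src * rep(as.numeric(mask), each = dims[1])
  out <- array(0, dims)
  for (r in seq_len(nrow(kernel))) {
    dz <- kernel[r, 1]; dy <- kernel[r, 2]; dx <- kernel[r, 3]
    z_dst <- max(1, 1 - dz):min(nz, nz - dz)
    y_dst <- max(1, 1 - dy):min(ny, ny - dy)
    x_dst <- max(1, 1 - dx):min(nx, nx - dx)
    if (!length(z_dst) || !length(y_dst) || !length(x_dst)) next
    out[, z_dst, y_dst, x_dst] <- out[, z_dst, y_dst, x_dst, drop = FALSE] +
      src[, z_dst + dz, y_dst + dy, x_dst + dx, drop = FALSE]
  }
  out <- out * rep(as.numeric(mask), each = dims[1])
  flim_stack(out, stack$config, stack$voxel_size)
}

#' Exclude voxels with insufficient binned counts
#'
#' Removes from the mask the voxels whose post-binning photon total does not
#' strictly exceed `min_count` (500 by default), below which curve fitting is
#' unreliable.
#'
#' @param binned A binned [flim_stack()] from [spatial_bin()].
#' @param mask 3D logical array.
#' @param min_count Photon floor; totals `<= min_count` are excluded.
#' @return The filtered logical mask.
#' @export
exclude_low_counts <- function(binned, mask, min_count = 500) {
  totals <- voxel_totals(binned)
  if (!identical(dim(totals), dim(mask))) stopf("mask dimensions must match stack")
  mask & (totals > min_count)
}
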