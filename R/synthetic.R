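#' Sample a Poisson photon-count decay histogram
#'
#' Draws per-bin counts independently as `Poisson(C * s_i)`, where `s` is the
#' forward model curve of the given parameters (decay convolved with the IRF
#' under periodic excitation, normalised, plus background). The expected
#' total count is `C`.
#'
#' @param params A [decay_params()].
#' @param irf A `flim_irf`.
#' @param config A [flim_acquisition()].
#' @param C Expected total photon count, positive.
#' @param seed Optional seed; when given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param oversample Model quadrature sub-samples per bin.
#' @return Integer vector of counts, one per time bin.
#' @examples
#' h <- sample_decay_counts(decay_params(0.7, 3.5), irf_gaussian(),
#'                          flim_acquisition(), C = 2000, seed = 1)
#' sum(h)
#' @export
sample_decay_counts <- function(params, irf, config, C, seed = NULL,
                                oversample = 8L) {
  if (C <= 0) stopf("C must be positive")
  s <- model_probabilities(params, irf, config, oversample)
  with_seed(seed, rpois(config$n_bins, C * s))
}

#' Specify a synthetic FLIM phantom
#'
#' Describes a ground-truth 4D phantom: labelled geometric regions with known
#' decay parameters and photon budgets, optional bright non-biological
#' outlier voxels (emulating tracheae), and a noisy marker channel covering
#' the marker-positive regions. Defaults emulate in vivo NAD(P)H acquisitions:
#' 129 bins over a 12.5 ns period, 0.4 um lateral / 2 um axial voxels, free
#' fractions around 0.65-0.75, bound lifetimes of 3-4 ns and 150-300 photons
#' per voxel before binning.
#'
#' @param shape Integer `(z, y, x)` image extent in voxels.
#' @param voxel_size `(z, y, x)` voxel size in micrometres.
#' @param regions List of region specs, each a list with `label` (character),
#'   `geometry` (list with `type` = `"box"`, `"sphere"` or `"shell"` and its
#'   extent: `zlim`/`ylim`/`xlim` for boxes, `center` and `radius`
#'   (+ `inner_radius` for shells, in voxel units) otherwise), `params`
#'   (a [decay_params()]), `photon_budget` (mean photons per voxel) and
#'   optionally `marker_positive` (default `TRUE`). Later regions overwrite
#'   earlier ones where they overlap.
#' @param outlier_spec List with `n` (number of bright voxels) and
#'   `multiplier` (photon-budget multiplier); `NULL` for none.
#' @param marker_spec List with `intensity` (marker level in positive
#'   regions) and `noise_sd` (Gaussian intensity noise).
#' @param acquisition A [flim_acquisition()].
#' @param irf A `flim_irf`.
#' @param rng_seed Integer seed controlling every random element.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(1L, 16L, 26L),
                         voxel_size = c(2, 0.4, 0.4),
                         regions = list(
                           list(label = "somata",
                                geometry = list(type = "box",
                                                zlim = c(1, 1),
                                                ylim = c(3, 14),
                                                xlim = c(3, 12)),
                                params = decay_params(0.68, 3.67),
                                photon_budget = 250),
                           list(label = "calyx",
                                geometry = list(type = "box",
                                                zlim = c(1, 1),
                                                ylim = c(3, 14),
                                                xlim = c(15, 24)),
                                params = decay_params(0.75, 3.4),
                                photon_budget = 250)),
                         outlier_spec = list(n = 2L, multiplier = 20),
                         marker_spec = list(intensity = 100, noise_sd = 10),
                         acquisition = flim_acquisition(),
                         irf = irf_gaussian(),
                         rng_seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("shape must be 3 positive integers")
  for (rg in regions) {
    if (is.null(rg$label) || is.null(rg$geometry) || is.null(rg$params) ||
        is.null(rg$photon_budget))
      stopf("each region needs label, geometry, params and photon_budget")
    if (rg$photon_budget <= 0) stopf("photon budgets must be positive")
  }
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 regions = regions, outlier_spec = outlier_spec,
                 marker_spec = marker_spec, acquisition = acquisition,
                 irf = irf, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# rasterise one region geometry into a logical volume
.rasterise_geometry <- function(geom, shape) {
  vol <- array(FALSE, shape)
  if (geom$type == "box") {
    vol[geom$zlim[1]:geom$zlim[2], geom$ylim[1]:geom$ylim[2],
        geom$xlim[1]:geom$xlim[2]] <- TRUE
  } else {
    idx <- expand.grid(z = seq_len(shape[1]), y = seq_len(shape[2]),
                       x = seq_len(shape[3]))
    d2 <- (idx$z - geom$center[1])^2 + (idx$y - geom$center[2])^2 +
          (idx$x - geom$center[3])^2
    inside <- d2 <= geom$radius^2
    if (geom$type == "shell") inside <- inside & d2 >= geom$inner_radius^2
    vol[as.matrix(idx)[inside, , drop = FALSE]] <- TRUE
  }
  vol
}

#' Generate a ground-truth FLIM phantom
#'
#' Voxelises the region geometries (later regions win where they overlap),
#' samples every region voxel's decay histogram via [sample_decay_counts()],
#' injects bright outlier voxels by multiplying their photon budget, and
#' builds a marker channel as region indicator times intensity plus Gaussian
#' noise. Ground-truth parameter maps and masks are returned alongside, so
#' every pipeline stage can be checked against the known truth.
#'
#' @param spec A [phantom_spec()].
#' @return List with `flim` (a [flim_stack()]), `marker` (a
#'   [marker_stack()]), `truth` (list of 3D arrays `f_free`, `tau_bound`,
#'   `label`), `masks` (named list of per-region logical masks plus
#'   `all`), and `outlier_voxels` (index matrix of injected outliers).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  cfg <- spec$acquisition
  label <- array(0L, shape)
  f_true <- array(NA_real_, shape)
  tb_true <- array(NA_real_, shape)
  budget <- array(0, shape)
  masks <- list()
  for (k in seq_along(spec$regions)) {
    rg <- spec$regions[[k]]
    vol <- .rasterise_geometry(rg$geometry, shape)
    label[vol] <- k
    f_true[vol] <- rg$params$f_free
    tb_true[vol] <- rg$params$tau_bound
    budget[vol] <- rg$photon_budget
  }
  for (k in seq_along(spec$regions))
    masks[[spec$regions[[k]]$label]] <- label == k
  masks$all <- label > 0L
  with_seed(spec$rng_seed, {
    # bright non-biological outliers (tracheae-like)
    outliers <- matrix(integer(0), 0, 3)
    if (!is.null(spec$outlier_spec) && spec$outlier_spec$n > 0) {
      cand <- which(label > 0L)
      pick <- sample(cand, min(spec$outlier_spec$n, length(cand)))
      budget[pick] <- budget[pick] * spec$outlier_spec$multiplier
      outliers <- arrayInd(pick, shape)
    }
    counts <- array(0, c(cfg$n_bins, shape))
    in_any <- which(label > 0L)
    # one model curve per region; Poisson draws per voxel
    s_by_region <- lapply(spec$regions, function(rg)
      model_probabilities(rg$params, spec$irf, cfg))
    for (i in in_any) {
      zyx <- arrayInd(i, shape)
      s <- s_by_region[[label[i]]]
      counts[, zyx[1], zyx[2], zyx[3]] <- rpois(cfg$n_bins, budget[i] * s)
    }
    marker_pos <- array(FALSE, shape)
    for (k in seq_along(spec$regions)) {
      rg <- spec$regions[[k]]
      if (isTRUE(rg$marker_positive %||% TRUE)) marker_pos <- marker_pos | (label == k)
    }
    marker <- spec$marker_spec$intensity * marker_pos +
      array(rnorm(prod(shape), 0, spec$marker_spec$noise_sd), shape)
    list(flim = flim_stack(counts, cfg, spec$voxel_size),
         marker = marker_stack(pmax(marker, 0), spec$voxel_size, "cytosolic"),
         truth = list(f_free = f_true, tau_bound = tb_true, label = label),
         masks = masks,
         outlier_voxels = outliers)
  })
}
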