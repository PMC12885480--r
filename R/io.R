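#' Read and write FLIM stacks
#'
#' A stack is stored as a multi-page 32-bit float TIFF plus a JSON sidecar.
#' Pages are ordered time-major: page `(t - 1) * n_z + z` holds time bin `t`
#' of slice `z` (axis order `TZYX`). Because TIFF floats are constrained to
#' `[0, 1]`, counts are divided by a scale factor recorded in the sidecar
#' (`count_scale`) and re-multiplied and rounded on read; counts up to 2^24
#' round-trip exactly. The sidecar records `n_bins`, `period_T_ns`,
#' `bin_width_ns`, `voxel_size_um` and `axis_order`.
#'
#' @param stack A [flim_stack()].
#' @param path Path of the TIFF file; the sidecar is `<path>.json`.
#' @return [read_flim_stack()] returns a [flim_stack()];
#'   [write_flim_stack()] returns `path` invisibly.
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  d <- dim(stack$counts)
  scale <- max(stack$counts, 1)
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1]))
    for (z in seq_len(d[2]))
      pages[[(t - 1) * d[2] + z]] <-
        matrix(stack$counts[t, z, , ] / scale, d[3], d[4])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(n_bins = stack$config$n_bins,
                  period_T_ns = stack$config$period_T,
                  bin_width_ns = stack$config$bin_width,
                  time_origin_ns = stack$config$time_origin,
                  voxel_size_um = stack$voxel_size,
                  axis_order = "TZYX",
                  n_z = d[2],
                  count_scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_flim_stack
#' @export
read_flim_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stopf("missing sidecar %s", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  n_z <- sc$n_z
  if (length(pages) != sc$n_bins * n_z)
    stopf("page count (%d) does not match sidecar n_bins x n_z (%d x %d)",
          length(pages), sc$n_bins, n_z)
  d_yx <- dim(pages[[1]])
  counts <- array(0, c(sc$n_bins, n_z, d_yx[1], d_yx[2]))
  for (t in seq_len(sc$n_bins))
    for (z in seq_len(n_z))
      counts[t, z, , ] <- round(pages[[(t - 1) * n_z + z]] * sc$count_scale)
  if (any(counts < 0)) stopf("negative counts in %s", path)
  cfg <- flim_acquisition(period_T = sc$period_T_ns, n_bins = sc$n_bins,
                          bin_width = sc$bin_width_ns,
                          time_origin = sc$time_origin_ns %||% 0)
  flim_stack(counts, cfg, sc$voxel_size_um)
}

#' Read and write region masks
#'
#' Masks are stored as multi-page 8-bit TIFF label images, one page per Z
#' slice.
#'
#' @param mask 3D logical array.
#' @param path TIFF file path.
#' @return [read_mask()] returns a logical array; [write_mask()] returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask)[1]),
                  function(z) matrix(as.numeric(mask[z, , ]), dim(mask)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  out <- array(FALSE, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]] > 0.5
  out
}

#' Write fitted parameter maps with provenance
#'
#' Each parameter becomes one multi-page 32-bit float TIFF (one page per Z
#' slice, Z-major order; missing voxels as zero with a companion validity
#' page convention is avoided — a long-format CSV carries exact values). A
#' JSON sidecar records thresholds, the fixed time shift, the seed and
#' exclusion counts, and a long-format CSV lists every fitted voxel.
#'
#' @param maps A `flim_maps` object from [fit_image()].
#' @param dir Output directory (created if needed).
#' @param report Optional named exclusion counts from
#'   [apply_quality_filters()].
#' @param fit_cfg The [fit_config()] used (for threshold provenance).
#' @return The directory path, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, report = NULL,
                                 fit_cfg = fit_config()) {
  stopifnot(inherits(maps, "flim_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  par_names <- c("f_free", "tau_bound", "delta_t", "background_b",
                 "two_i_star")
  scales <- list()
  for (nm in par_names) {
    m <- maps[[nm]]
    sc <- max(abs(m), 1, na.rm = TRUE)
    scales[[nm]] <- sc
    vals <- m / (2 * sc) + 0.5        # map to [0, 1] keeping sign
    vals[is.na(vals)] <- 0
    pages <- lapply(seq_len(dim(m)[1]),
                    function(z) matrix(vals[z, , ], dim(m)[2]))
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  idx <- which(!is.na(maps$f_free), arr.ind = TRUE)
  tab <- data.frame(z = idx[, 1], y = idx[, 2], x = idx[, 3])
  for (nm in par_names) tab[[nm]] <- maps[[nm]][idx]
  write.csv(tab, file.path(dir, "voxels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(median_delta_t = maps$provenance$median_delta_t,
         seed = maps$provenance$seed,
         n_step1 = maps$provenance$n_step1,
         n_step2 = maps$provenance$n_step2,
         max_two_i_star = fit_cfg$max_two_i_star,
         min_f_free = fit_cfg$min_f_free,
         min_binned_count = fit_cfg$min_binned_count,
         exclusions = as.list(report %||% list()),
         map_scales = scales,
         package_version = as.character(utils::packageVersion("flimpipe"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full FLIM analysis pipeline on one image
#'
#' Executes the processing chain used for each acquisition: segment the
#' marker channel (unless a mask is supplied), exclude bright outlier voxels,
#' spatially bin the decay histograms, exclude low-count voxels, fit the
#' decay model in two steps, apply the post-fit quality filters and summarise
#' the requested regions.
#'
#' @param stack A [flim_stack()] or path readable by [read_flim_stack()].
#' @param marker A [marker_stack()] (ignored when `mask` is given).
#' @param irf A `flim_irf`.
#' @param recipe Segmentation recipe or preset name (see
#'   [segmentation_preset()]).
#' @param mask Optional precomputed 3D logical mask, bypassing segmentation.
#' @param regions Optional named list of region masks to summarise; when
#'   `NULL` the whole fitted mask is summarised as one region.
#' @param fit_cfg A [fit_config()].
#' @param subject_id,hemisphere Identifiers attached to the summaries.
#' @param out_dir Optional directory; when given, parameter maps, provenance
#'   and summary CSVs are written there.
#' @return List of class `flim_run` with `maps` (filtered `flim_maps`),
#'   `mask` (final fitted mask), `summaries` (`data.frame`), `exclusions`
#'   (named counts per stage) and `provenance`.
#' @export
run_pipeline <- function(stack, marker = NULL, irf = irf_gaussian(),
                         recipe = "mb_cytosolic", mask = NULL,
                         regions = NULL, fit_cfg = fit_config(),
                         subject_id = NA_character_,
                         hemisphere = NA_character_, out_dir = NULL) {
  if (is.character(stack)) stack <- read_flim_stack(stack)
  stopifnot(inherits(stack, "flim_stack"))
  if (is.null(mask)) {
    if (is.null(marker)) stopf("either a marker stack or a mask is required")
    mask <- segment_marker(marker, recipe)
  }
  n0 <- sum(mask)
  mask1 <- exclude_bright_outliers(stack, mask)
  binned <- spatial_bin(stack, mask1)
  mask2 <- exclude_low_counts(binned, mask1, fit_cfg$min_binned_count)
  maps <- fit_image(binned, mask2, irf, fit_cfg)
  fl <- apply_quality_filters(maps, fit_cfg)
  exclusions <- c(segmented = n0,
                  bright_outliers = n0 - sum(mask1),
                  low_counts = sum(mask1) - sum(mask2),
                  fl$report)
  if (is.null(regions)) regions <- list(all = mask2)
  summaries <- do.call(rbind, lapply(names(regions), function(rn) {
    summarize_region(fl$maps$f_free, regions[[rn]] & mask2,
                     subject_id = subject_id, region = rn,
                     hemisphere = hemisphere)
  }))
  if (!is.null(summaries)) {
    tb <- vapply(names(regions), function(rn) {
      v <- fl$maps$tau_bound[regions[[rn]] & mask2]
      mean(v[!is.na(v)])
    }, numeric(1))
    summaries$mean_tau_bound <- tb[summaries$region]
  }
  res <- structure(list(maps = fl$maps, mask = mask2, summaries = summaries,
                        exclusions = exclusions,
                        provenance = maps$provenance),
                   class = "flim_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_parameter_maps(fl$maps, out_dir, fl$report, fit_cfg)
    if (!is.null(summaries))
      write.csv(summaries, file.path(out_dir, "summaries.csv"),
                row.names = FALSE)
    jsonlite::write_json(as.list(exclusions),
                         file.path(out_dir, "exclusions.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.flim_run <- function(x, ...) {
  cat(sprintf("flim_run: %d voxels fitted (median dt %.4g ns)\n",
              sum(!is.na(x$maps$f_free)), x$provenance$median_delta_t))
  if (!is.null(x$summaries)) print(x$summaries)
  invisible(x)
}
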