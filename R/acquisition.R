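#' Acquisition configuration for a TCSPC FLIM recording
#'
#' Describes the time axis of the photon-arrival histograms: the laser period,
#' the number of time bins and their width. Bin centres are placed at
#' `time_origin + (i - 1/2) * bin_width`, the usual TCSPC convention in which
#' the first bin starts at the laser pulse.
#'
#' @param period_T Laser period in ns (12.5 ns for an 80 MHz source).
#' @param n_bins Number of time bins of the decay histograms.
#' @param bin_width Width of one bin in ns; defaults to `period_T / n_bins` so
#'   the acquisition window tiles the full period.
#' @param time_origin Offset of the start of the first bin in ns.
#'
#' @return An object of class `flim_acquisition`.
#' @examples
#' cfg <- flim_acquisition()
#' head(bin_times(cfg))
#' @export
flim_acquisition <- function(period_T = 12.5, n_bins = 129L,
                             bin_width = period_T / n_bins,
                             time_origin = 0) {
  assert_finite(period_T, "period_T"); assert_finite(bin_width, "bin_width")
  if (period_T <= 0) stopf("period_T must be positive")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stopf("n_bins must be an integer >= 2")
  if (bin_width <= 0) stopf("bin_width must be positive")
  if (n_bins * bin_width > period_T + bin_width + 1e-9)
    stopf("acquisition window (%d x %.4g ns) exceeds one laser period (%.4g ns)",
          n_bins, bin_width, period_T)
  structure(
    list(period_T = period_T, n_bins = n_bins, bin_width = bin_width,
         time_origin = time_origin),
    class = "flim_acquisition"
  )
}

#' Bin-centre times of an acquisition configuration
#'
#' @param config A [flim_acquisition()] object.
#' @return Numeric vector of bin-centre times in ns.
#' @export
bin_times <- function(config) {
  config$time_origin + (seq_len(config$n_bins) - 0.5) * config$bin_width
}

# Number of bins making up one full laser period on this grid (the lag of the
# previous-pulse term). For the default grid this equals n_bins.
bins_per_period <- function(config) {
  n_per <- round(config$period_T / config$bin_width)
  if (abs(n_per * config$bin_width - config$period_T) > 1e-6 * config$period_T)
    stopf("laser period must be an integer number of bins (got %.6g bins)",
          config$period_T / config$bin_width)
  as.integer(n_per)
}

#' @export
print.flim_acquisition <- function(x, ...) {
  cat(sprintf("FLIM acquisition: %d bins of %.4f ns, period %.4g ns\n",
              x$n_bins, x$bin_width, x$period_T))
  invisible(x)
}
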