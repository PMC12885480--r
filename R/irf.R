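#' Instrument response functions
#'
#' The IRF describes the temporal blur the microscope applies to an
#' instantaneous emission event. Two representations are supported:
#'
#' * a *measured histogram* on the same bin grid as the decay data
#'   ([irf_histogram()]), convolved with the decay by discrete convolution in
#'   which bin `j` acts at lag `(j - 1)` bins (so a unit mass in the first bin
#'   is the identity kernel);
#' * a *parametric Gaussian* ([irf_gaussian()]) with a centre and FWHM in ns,
#'   convolved with the decay on an oversampled grid using its continuous form.
#'
#' The model curve is invariant under rescaling of the IRF by any positive
#' constant, so histograms need not be normalised.
#'
#' @param values Nonnegative per-bin weights (measured histogram).
#' @param center Centre of the Gaussian IRF in ns.
#' @param fwhm Full width at half maximum in ns.
#' @return An object of class `flim_irf`.
#' @examples
#' irf_gaussian()                      # default: centre 0.5 ns, FWHM 0.2 ns
#' irf_histogram(c(1, rep(0, 128)))    # delta kernel
#' @name irf
NULL

#' @rdname irf
#' @export
irf_histogram <- function(values) {
  assert_finite(values, "values")
  if (any(values < 0)) stopf("IRF values must be nonnegative")
  if (sum(values) <= 0) stopf("degenerate IRF: all values are zero")
  structure(list(kind = "histogram", values = as.numeric(values)),
            class = "flim_irf")
}

#' @rdname irf
#' @export
irf_gaussian <- function(center = 0.5, fwhm = 0.2) {
  assert_finite(center, "center"); assert_finite(fwhm, "fwhm")
  if (fwhm <= 0) stopf("fwhm must be positive")
  structure(list(kind = "gaussian", center = center, fwhm = fwhm,
                 sigma = fwhm / (2 * sqrt(2 * log(2)))),
            class = "flim_irf")
}

#' @export
print.flim_irf <- function(x, ...) {
  if (x$kind == "gaussian")
    cat(sprintf("Gaussian IRF: centre %.3g ns, FWHM %.3g ns\n", x$center, x$fwhm))
  else
    cat(sprintf("Measured IRF histogram: %d bins, total weight %.4g\n",
                length(x$values), sum(x$values)))
  invisible(x)
}

# Shift a histogram IRF by delta_t ns (possibly a fraction of a bin) by
# circular linear interpolation over the laser period. Positive shifts move
# the IRF to later times.
shift_irf_values <- function(values, delta_t, bin_width, n_per = length(values)) {
  v <- numeric(n_per)
  v[seq_along(values)] <- values
  shift <- delta_t / bin_width
  k <- floor(shift)
  w <- shift - k
  idx <- seq_len(n_per) - 1L
  i0 <- ((idx - k) %% n_per) + 1L
  i1 <- ((idx - k - 1) %% n_per) + 1L
  (1 - w) * v[i0] + w * v[i1]
}

#' Read or write an IRF
#'
#' Measured IRFs are stored as a two-column CSV (`time_ns`, `weight`);
#' parametric Gaussian IRFs as a JSON object `{"center": ..., "fwhm": ...}`.
#' The format is chosen from the file extension.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param irf A `flim_irf` object (for writing).
#' @return [read_irf()] returns a `flim_irf`; [write_irf()] returns `path`
#'   invisibly.
#' @export
read_irf <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    irf_gaussian(center = spec$center, fwhm = spec$fwhm)
  } else {
    tab <- read.csv(path)
    if (!all(c("time_ns", "weight") %in% names(tab)))
      stopf("IRF CSV must have columns time_ns and weight")
    irf_histogram(tab$weight)
  }
}

#' @rdname read_irf
#' @param config A [flim_acquisition()] supplying bin times when writing a
#'   histogram IRF.
#' @export
write_irf <- function(irf, path, config = flim_acquisition()) {
  if (irf$kind == "gaussian") {
    jsonlite::write_json(list(center = irf$center, fwhm = irf$fwhm), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(data.frame(time_ns = bin_times(config)[seq_along(irf$values)],
                         weight = irf$values),
              path, row.names = FALSE)
  }
  invisible(path)
}
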