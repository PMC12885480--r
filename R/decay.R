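#' Bi-exponential decay parameters
#'
#' The per-voxel metabolic state recovered from a NAD(P)H decay: the free
#' fraction `f_free`, the bound-pool lifetime `tau_bound` (ns), the fixed
#' free-pool lifetime `tau_free` (0.4 ns throughout, in line with the values
#' reported for aqueous solutions, cell cultures and in vivo tissue), the time
#' shift `delta_t` between IRF and signal, and a constant per-bin background
#' `background_b` added to the normalised model curve.
#'
#' @param f_free Free NAD(P)H fraction in `[0, 1]`.
#' @param tau_bound Bound NAD(P)H lifetime in ns, positive.
#' @param delta_t IRF/signal time shift in ns.
#' @param background_b Constant per-bin background, nonnegative.
#' @param tau_free Free NAD(P)H lifetime in ns (fixed during fitting).
#' @return An object of class `decay_params`.
#' @examples
#' p <- decay_params(f_free = 0.7, tau_bound = 3.5)
#' tau_mean(p)
#' @export
decay_params <- function(f_free, tau_bound, delta_t = 0, background_b = 0,
                         tau_free = 0.4) {
  for (nm in c("f_free", "tau_bound", "delta_t", "background_b", "tau_free"))
    assert_finite(get(nm), nm)
  if (f_free < 0 || f_free > 1) stopf("f_free must lie in [0, 1]")
  if (tau_free <= 0 || tau_bound <= 0) stopf("lifetimes must be positive")
  if (background_b < 0) stopf("background_b must be nonnegative")
  structure(list(f_free = f_free, tau_free = tau_free, tau_bound = tau_bound,
                 delta_t = delta_t, background_b = background_b),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf(
    "decay_params: f_free %.3f, tau_free %.3g ns, tau_bound %.3g ns, dt %.3g ns, b %.3g\n",
    x$f_free, x$tau_free, x$tau_bound, x$delta_t, x$background_b))
  invisible(x)
}

#' Evaluate the ideal bi-exponential decay
#'
#' `d(t) = f_free exp(-t / tau_free) + (1 - f_free) exp(-t / tau_bound)`,
#' the fluorescence impulse response of a two-pool NAD(P)H mixture.
#'
#' @param params A [decay_params()] object.
#' @param times Nonnegative times in ns.
#' @return Unitless decay values, one per time.
#' @export
evaluate_decay <- function(params, times) {
  stopifnot(inherits(params, "decay_params"))
  assert_finite(times, "times")
  if (any(times < 0)) stopf("times must be nonnegative")
  params$f_free * exp(-times / params$tau_free) +
    (1 - params$f_free) * exp(-times / params$tau_bound)
}

#' Model curve under IRF convolution and periodic excitation
#'
#' Evaluates the measured-signal model
#' `f(t_i) = sum_{p in {0,1}} (d * IRF)(t_i - delta_t + p T)`:
#' the ideal decay convolved with the instrument response, including the
#' fluorescence still decaying from the previous laser pulse (`p = 1`). The
#' decay is oversampled within each bin and box-averaged, so `f` approximates
#' the bin-integrated signal.
#'
#' @param params A [decay_params()] (its `delta_t` shifts the IRF).
#' @param irf A [irf_histogram()] or [irf_gaussian()] object.
#' @param config A [flim_acquisition()].
#' @param oversample Sub-samples per bin used for the decay quadrature;
#'   `oversample = 1` samples bin centres, under which a delta IRF reproduces
#'   `d(t_i) + d(t_i + T)` exactly.
#' @return Nonnegative unnormalised model values `f(t_i)`, one per bin.
#' @seealso [normalize_with_background()] for the probability-per-bin curve.
#' @export
apply_irf_periodic <- function(params, irf, config, oversample = 8L) {
  stopifnot(inherits(params, "decay_params"), inherits(irf, "flim_irf"),
            inherits(config, "flim_acquisition"))
  oversample <- as.integer(oversample)
  if (oversample < 1L) stopf("oversample must be >= 1")
  n_per <- bins_per_period(config)
  if (config$n_bins > n_per)
    stopf("n_bins must not exceed the bins in one laser period")
  if (irf$kind == "gaussian") {
    f <- cpp_model_gauss(params$f_free, params$tau_free, params$tau_bound,
                         irf$center + params$delta_t, irf$sigma,
                         config$n_bins, n_per, config$bin_width, oversample)
  } else {
    v <- shift_irf_values(irf$values, params$delta_t, config$bin_width, n_per)
    f <- cpp_model_hist(params$f_free, params$tau_free, params$tau_bound,
                        v, config$n_bins, n_per, config$bin_width, oversample)
  }
  pmax(f, 0)
}

#' Normalise a model curve and add constant background
#'
#' First normalises the raw curve, `f_i = f(t_i) / sum_j f(t_j)`, then folds in
#' a constant per-bin background `b`:
#' `s_i = (f_i + b) / sum_j (f_j + b)`. The result is the per-bin photon
#' probability used by the Poisson likelihood; it always sums to one.
#'
#' @param f_values Nonnegative unnormalised model values, not all zero.
#' @param background_b Constant per-bin background, nonnegative.
#' @return List with `f_values` (normalised curve) and `s_values`
#'   (probabilities including background), both summing to one.
#' @export
normalize_with_background <- function(f_values, background_b = 0) {
  assert_finite(f_values, "f_values")
  if (background_b < 0) stopf("invalid parameter: background_b must be >= 0")
  if (any(f_values < 0)) stopf("f_values must be nonnegative")
  tot <- sum(f_values)
  if (tot <= 0) stopf("f_values must not be all zero")
  f_norm <- f_values / tot
  s <- (f_norm + background_b) / (1 + length(f_values) * background_b)
  list(f_values = f_norm, s_values = s)
}

# Full forward model: probability per bin for given params / IRF / grid.
model_probabilities <- function(params, irf, config, oversample = 8L) {
  f <- apply_irf_periodic(params, irf, config, oversample)
  normalize_with_background(f, params$background_b)$s_values
}

#' Mean fluorescence lifetime
#'
#' `tau_mean = f_free tau_free + (1 - f_free) tau_bound`, the fraction-weighted
#' mean of the free and bound NAD(P)H lifetimes.
#'
#' @param params A [decay_params()] object.
#' @return Mean lifetime in ns.
#' @export
tau_mean <- function(params) {
  stopifnot(inherits(params, "decay_params"))
  params$f_free * params$tau_free + (1 - params$f_free) * params$tau_bound
}
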