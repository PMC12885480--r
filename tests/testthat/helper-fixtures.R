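# Shared fixtures: small acquisition grids, delta IRFs, and an independent
# dense-grid convolution oracle for the Gaussian-IRF model.

toy_config <- function(n_bins = 8L, period = 12.5) {
  flim_acquisition(period_T = period, n_bins = n_bins,
                   bin_width = period / n_bins)
}

delta_irf <- function(n_bins = 129L) irf_histogram(c(1, rep(0, n_bins - 1L)))

# Brute-force oracle: bi-exponential decay convolved with a continuous
# Gaussian IRF on a x64 oversampled grid, previous-pulse term added, then
# box-averaged per bin. Independent of the package's C++ path.
dense_gauss_oracle <- function(params, center, fwhm, config, os = 64L) {
  h <- config$bin_width / os
  n_per <- round(config$period_T / config$bin_width)
  tfine <- (seq_len(2L * n_per * os) - 0.5) * h
  dfine <- params$f_free * exp(-tfine / params$tau_free) +
    (1 - params$f_free) * exp(-tfine / params$tau_bound)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  q <- 0:ceiling((center + 6 * sig) / h)
  w <- exp(-0.5 * ((q * h - center) / sig)^2)
  w <- w / sum(w)
  cfull <- rep(0, length(tfine))
  for (j in seq_along(q)) {
    qq <- q[j]
    idx <- (qq + 1):length(tfine)
    cfull[idx] <- cfull[idx] + w[j] * dfine[idx - qq]
  }
  ffine <- cfull[seq_len(config$n_bins * os)] +
    cfull[n_per * os + seq_len(config$n_bins * os)]
  colMeans(matrix(ffine, nrow = os))
}

# Independent R-side deviance for a delta-IRF model on bin centres
# (closed-form decay, no shared code with the fitted path beyond
# evaluate_decay).
delta_irf_deviance <- function(counts, f_free, tau_bound, b, config,
                               tau_free = 0.4) {
  tt <- bin_times(config)
  p <- decay_params(f_free, tau_bound, tau_free = tau_free)
  d <- evaluate_decay(p, tt) + evaluate_decay(p, tt + config$period_T)
  fn <- d / sum(d)
  s <- (fn + b) / (1 + config$n_bins * b)
  C <- sum(counts)
  pos <- counts > 0
  2 * sum(counts[pos] * log(counts[pos] / (C * s[pos])))
}
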