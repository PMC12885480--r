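#include <Rcpp.h>
using namespace Rcpp;

// Bi-exponential decay sampled at fine-grid midpoints t_m = (m + 0.5) h,
// m = 0 .. n_fine - 1, via multiplicative recurrence (two exp calls total).
static void fill_dfine(std::vector<double> &d, int n_fine, double h,
                       double f_free, double tau_free, double tau_bound) {
  const double rf = std::exp(-h / tau_free), rb = std::exp(-h / tau_bound);
  double vf = f_free * std::exp(-0.5 * h / tau_free);
  double vb = (1.0 - f_free) * std::exp(-0.5 * h / tau_bound);
  for (int m = 0; m < n_fine; ++m) {
    d[m] = vf + vb;
    vf *= rf;
    vb *= rb;
  }
}

// Model curve for a Gaussian IRF centred at `center` (ns): the decay is
// convolved with the IRF sampled at lags q*h (truncated at +-6 sigma and at
// time zero), the previous-pulse term is added, and the result is
// box-averaged over the `os` sub-samples of each bin. The box average and
// IRF are folded into one combined kernel so only n_bins outputs are formed.
static bool model_gauss(std::vector<double> &f, double f_free,
                        double tau_free, double tau_bound, double center,
                        double sigma, int n_bins, int n_per, double bw,
                        int os) {
  const double h = bw / os;
  const int n_fine = 2 * n_per * os;
  std::vector<double> dfine(n_fine);
  fill_dfine(dfine, n_fine, h, f_free, tau_free, tau_bound);
  int q0 = (int)std::floor((center - 6.0 * sigma) / h);
  if (q0 < 0) q0 = 0;
  int q1 = (int)std::ceil((center + 6.0 * sigma) / h);
  if (q1 < q0) return false;          // kernel entirely before time zero
  if (q1 > n_per * os) return false;  // kernel centre beyond one period
  const int L = q1 - q0 + 1;
  std::vector<double> w(L);
  double wsum = 0.0;
  for (int q = 0; q < L; ++q) {
    double z = ((q + q0) * h - center) / sigma;
    w[q] = std::exp(-0.5 * z * z);
    wsum += w[q];
  }
  if (wsum <= 0.0) return false;
  // combined kernel: coefficient of dfine[i*os + u - q0] in the box average
  // f[i] = (1/os) sum_{j=0}^{os-1} sum_q w[q] dfine[i*os + j - q - q0]
  const int u_lo = -(L - 1), u_hi = os - 1;
  std::vector<double> wc(u_hi - u_lo + 1, 0.0);
  for (int u = u_lo; u <= u_hi; ++u) {
    int qa = std::max(0, -u), qb = std::min(L - 1, os - 1 - u);
    double acc = 0.0;
    for (int q = qa; q <= qb; ++q) acc += w[q];
    wc[u - u_lo] = acc / (os * wsum);
  }
  // index bounds: with m = i*os - q0 + u, the previous-pulse index
  // m + n_per*os always lies inside the two-period fine grid, and m itself
  // only underruns zero for the first few bins, so the inner loops are
  // branch-free.
  const int shift = n_per * os;
  const int n_wc = u_hi - u_lo + 1;
  for (int i = 0; i < n_bins; ++i) {
    const int base = i * os - q0 + u_lo;
    double acc = 0.0;
    const int k_start = base < 0 ? -base : 0;
    const double *d2 = &dfine[base + shift];
    for (int k = 0; k < k_start && k < n_wc; ++k) acc += wc[k] * d2[k];
    const double *d1 = &dfine[base];
    for (int k = k_start; k < n_wc; ++k) acc += wc[k] * (d1[k] + d2[k]);
    f[i] = acc > 0.0 ? acc : 0.0;
  }
  return true;
}

// Model curve for a measured IRF histogram on the bin grid: classical
// discrete convolution in which bin j of the IRF acts at a lag of (j - 1)
// bins, applied to the box-averaged decay, plus the previous-pulse term.
static void model_hist(std::vector<double> &f, double f_free, double tau_free,
                       double tau_bound, const double *irf, int n_irf,
                       int n_bins, int n_per, double bw, int os) {
  const int n_ext = 2 * n_per;
  const double h = bw / os;
  std::vector<double> dfine(n_ext * os);
  fill_dfine(dfine, n_ext * os, h, f_free, tau_free, tau_bound);
  std::vector<double> dbar(n_ext);
  for (int k = 0; k < n_ext; ++k) {
    double acc = 0.0;
    for (int j = 0; j < os; ++j) acc += dfine[k * os + j];
    dbar[k] = acc / os;
  }
  for (int i = 0; i < n_bins; ++i) {
    double acc = 0.0;
    int jmax = std::min(i, n_irf - 1);
    for (int j = 0; j <= jmax; ++j) {
      if (irf[j] == 0.0) continue;
      acc += irf[j] * (dbar[i - j] + dbar[i - j + n_per]);
    }
    f[i] = acc > 0.0 ? acc : 0.0;
  }
}

// Poisson deviance of counts m against probabilities formed from the raw
// model curve f and a constant per-bin background b:
//   s_i = (f_i / sum_j f_j + b) / (1 + N b)
static double deviance_from_f(const std::vector<double> &f,
                              const double *counts, int n, double b) {
  double fsum = 0.0, C = 0.0;
  for (int i = 0; i < n; ++i) { fsum += f[i]; C += counts[i]; }
  if (fsum <= 0.0) return R_PosInf;
  const double denom = 1.0 + n * b;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = counts[i];
    if (m > 0.0) {
      double s = (f[i] / fsum + b) / denom;
      if (s <= 0.0) return R_PosInf;
      acc += m * std::log(m / (C * s));
    }
  }
  return 2.0 * acc;
}

// [[Rcpp::export(name = "cpp_model_gauss")]]
NumericVector cpp_model_gauss(double f_free, double tau_free, double tau_bound,
                              double center, double sigma, int n_bins,
                              int n_per, double bin_width, int oversample) {
  std::vector<double> f(n_bins);
  if (!model_gauss(f, f_free, tau_free, tau_bound, center, sigma, n_bins,
                   n_per, bin_width, oversample))
    stop("degenerate IRF: no mass inside the acquisition window");
  return NumericVector(f.begin(), f.end());
}

// [[Rcpp::export(name = "cpp_model_hist")]]
NumericVector cpp_model_hist(double f_free, double tau_free, double tau_bound,
                             NumericVector irf, int n_bins, int n_per,
                             double bin_width, int oversample) {
  std::vector<double> f(n_bins);
  model_hist(f, f_free, tau_free, tau_bound, irf.begin(), irf.size(), n_bins,
             n_per, bin_width, oversample);
  return NumericVector(f.begin(), f.end());
}

// [[Rcpp::export(name = "cpp_deviance_gauss")]]
double cpp_deviance_gauss(NumericVector counts, double f_free,
                          double tau_free, double tau_bound, double b,
                          double center, double sigma, int n_bins, int n_per,
                          double bin_width, int oversample) {
  std::vector<double> f(n_bins);
  if (!model_gauss(f, f_free, tau_free, tau_bound, center, sigma, n_bins,
                   n_per, bin_width, oversample))
    return R_PosInf;
  return deviance_from_f(f, counts.begin(), n_bins, b);
}

// [[Rcpp::export(name = "cpp_deviance_hist")]]
double cpp_deviance_hist(NumericVector counts, double f_free, double tau_free,
                         double tau_bound, double b, NumericVector irf,
                         int n_bins, int n_per, double bin_width,
                         int oversample) {
  std::vector<double> f(n_bins);
  model_hist(f, f_free, tau_free, tau_bound, irf.begin(), irf.size(), n_bins,
             n_per, bin_width, oversample);
  return deviance_from_f(f, counts.begin(), n_bins, b);
}

// [[Rcpp::export(name = "cpp_two_i_star")]]
double cpp_two_i_star(NumericVector counts, NumericVector s) {
  const int n = counts.size();
  double C = 0.0;
  for (int i = 0; i < n; ++i) C += counts[i];
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = counts[i];
    if (m > 0.0) {
      if (s[i] <= 0.0) return R_PosInf;
      acc += m * std::log(m / (C * s[i]));
    }
  }
  return 2.0 * acc;
}
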