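---
title: "Models and methods behind flimpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flimpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimpipe)
```

## The measurement and its model

Time-correlated single photon counting (TCSPC) FLIM records, for every voxel
of a 3D image, a histogram of photon arrival times relative to the laser
pulse. For NAD(P)H autofluorescence the decay is well described by a mixture
of two pools: free NAD(P)H with a short lifetime and protein-bound NAD(P)H
with a long one,

$$d(t) = f_{free}\, e^{-t/\tau_{free}} + (1 - f_{free})\, e^{-t/\tau_{bound}}.$$

`flimpipe` holds $\tau_{free}$ fixed at 0.4 ns. This value is consistently
reported across aqueous solutions, cell cultures, tissue and in vivo work,
and its physiological interpretation is limited; fixing it removes one badly
constrained dimension from the voxelwise optimisation. The free parameters
per voxel are $f_{free}$, $\tau_{bound}$, a time shift $\Delta t$ between
the instrument response and the signal, and a constant per-bin background
$b$.

What the detector sees is the decay convolved with the instrument response
function (IRF), under periodic excitation at laser period $T$ (12.5 ns for
an 80 MHz source). Because $\tau_{bound}$ is not small compared with $T$,
fluorescence from the previous pulse is still present in the recorded
window; the model therefore sums two pulse terms,

$$f(t_i) = \sum_{p \in \{0,1\}} (d * IRF)(t_i - \Delta t + pT),$$

evaluated on the acquisition grid of $N_t = 129$ bins. The curve is
normalised and the background folded in,

$$f_i = \frac{f(t_i)}{\sum_j f(t_j)}, \qquad
  s_i = \frac{f_i + b}{\sum_j (f_j + b)},$$

so $s$ is a proper per-bin photon probability.

### Discretisation choices

The continuous formulas leave the discrete grid open; the package fixes it
as follows.

* Bin centres sit at $t_i = (i - \tfrac12)\,\Delta$ with
  $\Delta = T / N_t$, the usual TCSPC convention in which the window starts
  at the pulse.
* The decay is oversampled 8× within each bin and box-averaged, so the
  model approximates the bin-integrated signal rather than a point sample.
  With `oversample = 1` the model degenerates to bin-centre sampling, under
  which a delta IRF reproduces $d(t_i) + d(t_i + T)$ exactly — a convenient
  closed form used in the tests.
* A *measured* IRF histogram convolves discretely on the bin grid, bin $j$
  acting at lag $j - 1$ (a unit mass in the first bin is the identity
  kernel). $\Delta t$ is applied as a circular, possibly fractional, shift
  of the IRF by linear interpolation; circular shifting conserves IRF mass
  under the periodic excitation.
* A *parametric Gaussian* IRF (default: centre 0.5 ns, FWHM 0.2 ns, typical
  of two-photon systems) uses its continuous form, sampled on the
  oversampled grid and truncated at ±6σ. The implementation folds the
  box average and the IRF into one combined kernel; it matches a 64×
  oversampled brute-force convolution to better than $10^{-3}$ relative.
* Smoothing boundary handling throughout the package is reflection.

## Maximum-likelihood fitting

Photon counts are Poisson, so the fit minimises the likelihood-ratio
deviance

$$2I^{*} = 2 \sum_i m_i \ln\!\frac{m_i}{C s_i},$$

with $m_i$ the measured counts and $C$ their total. $2I^*$ is zero exactly
at $m_i = C s_i$ and grows with misfit, which also makes it a per-voxel
goodness-of-fit score. Minimisation uses Nelder–Mead with 5 restarts drawn
uniformly from the initialisation ranges $f_{free} \in [0.2, 0.95]$,
$\tau_{bound} \in [1, 5]$ ns, $\Delta t \in [-1, 1]$ ns,
$b \in [0, 0.01]$; these bracket all values reported for NAD(P)H in the
lifetime literature. The simplex runs in a transformed space — logit for
$f_{free}$, log for $\tau_{bound}$ and $b$ — so bounds hold without
constrained optimisation. Tolerances are $10^{-6}$ (relative) with at most
2000 iterations per restart; the restart with the lowest deviance wins.
Restart draws derive from a base seed plus the voxel's linear index, so any
single voxel can be refitted reproducibly.

Whole images are fitted in two steps: a four-parameter fit on every third
voxel in X and Y, then $\Delta t$ is fixed at the (lower) median of those
estimates and the remaining three parameters are refitted on all masked
voxels. The time shift is an instrument property, not a biological one, so
estimating it once per image both stabilises and accelerates the fit. Both
steps run on the spatially binned data.

## Preprocessing

Three rules precede fitting, in this order:

1. **Bright-outlier exclusion.** Voxels whose total counts exceed
   $Q_3 + 3\,\mathrm{IQR}$ of the in-mask distribution are removed. These
   are non-biological structures (tracheae and stray bright objects);
   running this *before* binning stops them from being smeared into their
   neighbours. Quartiles use linear interpolation of order statistics
   (type 7), and are computed over in-mask voxels only.
2. **Spatial binning.** Each voxel's histogram is summed with its in-mask
   neighbours under a disk kernel — 5×5×1 voxels with the four corners
   excluded, 21 offsets — trading lateral resolution for photon counts. The
   kernel is flat in Z because the axial step (2 µm) is coarse relative to
   the lateral one (~0.4 µm). Borders are truncated without
   renormalisation: border voxels simply collect fewer photons and fall to
   the next rule.
3. **Count floor.** Voxels whose binned total does not strictly exceed 500
   photons are excluded as unreliable to fit.

After fitting, voxels with $2I^* > 200$ (poor fits) or $f_{free} < 0.2$
(in practice, voxels outside the tissue that slipped through segmentation)
are discarded; both thresholds are configurable in `fit_config()`.

## Segmentation recipes

Region masks come from co-registered marker channels via Gaussian smoothing
followed by thresholding. The σ of the smoothing is given in micrometres and
converted to voxels per axis, so the physical blur is isotropic despite
anisotropic sampling. The registered presets are: Li thresholding at σ = 2 µm
keeping the largest contiguous volume (cytosolic whole-MB marker); a
two-step Li recipe at σ = 0.5 µm with a 1 µm³ minimum component volume
(nuclear subtype markers); and 3-class multi-Otsu keeping the class above
the highest threshold at σ = 3 µm and σ = 5 µm (somata and calyx template
masks). Contiguity uses 26-connectivity; the choice is not critical for
blob-like structures but is fixed and tested. Histogram specification
against a reference (for normalising marker images across a dataset) uses
the exact step-inverse CDF for sample references, making self-matching the
identity.

## Group statistics

Per region and subject the package reports the unweighted mean, sample
variance and adjusted Fisher–Pearson skewness of the valid voxels; variance
and skewness let one check that a group effect is a shift of the mean
rather than a reshaping of the distribution. Hemisphere summaries pool to
one value per subject — equal weights by default, voxel-weighted on
request. Group tests are the classical ones: pooled-variance two-tailed
Student's t (Welch optional, off by default), one-way ANOVA with optional
Bonferroni-adjusted post-hoc pairs, paired t, and repeated-measures ANOVA
with subject as blocking factor. Every test is also available from
summary statistics `(n, mean, SD)` alone, because published group
comparisons are stated in exactly that form; the summary-statistic path is
algebraically identical to the raw-sample path and tested as such.

## The fit-artifact simulation

Multi-exponential fitting can induce spurious correlation between parameter
estimates, which matters when interpreting an observed
$f_{free}$–$\tau_{bound}$ anticorrelation. `run_artifact_simulation()`
samples true parameter pairs *independently* (uniform over
$f_{free} \in [0.6, 0.8]$, $\tau_{bound} \in [3.0, 4.2]$ ns, the range
observed in vivo), generates Poisson decays, fits each with the pipeline's
own estimator and compares the correlation of the fitted pairs with that of
the true pairs. At $C = 10^6$ photons the fitted correlation tracks the
(near-zero) truth; at realistic counts ($C \sim 10^3$) estimation noise
induces a modest *positive* correlation between the estimates — the
opposite sign of the biological observation, reinforcing that an observed
anticorrelation is not produced by the fit. The report carries the seed and
full configuration needed to rerun bit-identically.

## The synthetic phantom

`phantom_spec()` describes ground-truth scenes; its defaults are the
conditions the pipeline is validated under, not tuning knobs:

* acquisition: 129 bins over 12.5 ns; voxels 0.4 µm laterally, 2 µm
  axially; Gaussian IRF (0.5 ns centre, 0.2 ns FWHM);
* two box regions in one Z slice emulating the somata region
  ($f_{free} = 0.68$, $\tau_{bound} = 3.67$ ns) and the calyx
  ($f_{free} = 0.75$, $\tau_{bound} = 3.40$ ns), 120 voxels each,
  separated by a two-voxel unlabelled gap so that the binning kernel cannot
  mix decays across the boundary while smoothing still segments the pair as
  one object;
* 250 expected photons per voxel before binning (the in vivo acquisitions
  average 150–300), putting binned interior totals near $21 \times 250
  \approx 5\times10^3$, comfortably above the 500-photon floor;
* two bright outlier voxels at 20× budget, exercising the
  $Q_3 + 3\,\mathrm{IQR}$ rule;
* a cytosolic marker channel at intensity 100 with Gaussian noise
  (SD 10).

Phantom sizes throughout the package's tests are desk-scale choices: large
enough that each region keeps ~70–110 fitted voxels after exclusions,
small enough that a ten-subject end-to-end study fits in about a minute.
The simulation reproduces Poisson photon statistics, region geometry,
marker contrast and bright artifacts. It does **not** model optical
blurring between regions, detector afterpulsing or pile-up, motion, or
anatomical variability — so passing phantom tests validates the estimator
and plumbing, not robustness to those real-data effects.

```{r phantom, eval = FALSE}
ph  <- generate_phantom(phantom_spec(rng_seed = 1))
run <- run_pipeline(ph$flim, ph$marker, irf_gaussian(),
                    recipe = "mb_cytosolic",
                    regions = ph$masks[c("somata", "calyx")],
                    fit_cfg = fit_config(rng_seed = 2))
run$summaries
```

## Degenerate inputs and tie-breaks

* An all-zero IRF, negative background, or non-finite parameters raise
  errors; a model probability of zero under observed counts yields an
  infinite deviance, never an exception.
* Empty masks and empty segmentation foregrounds warn and return empty
  results.
* The median used to fix $\Delta t$ is the lower median, a deterministic
  tie-break for even counts.
* Equal paired vectors give $t = 0, p = 1$; a constant nonzero shift gives
  an infinite-t sentinel with $p \to 0$.
* Fewer than four in-mask voxels make quartiles meaningless; the outlier
  filter then passes the mask through with a warning.

## Known limitations

* The bi-exponential model is the standard workhorse for NAD(P)H but is a
  simplification; tri-exponential and phasor analyses are out of scope.
* $\tau_{bound}$ estimates at low counts are noticeably noisier than
  $f_{free}$ (RMSE ≈ 0.3 ns at 1000 photons) and carry a small negative
  bias; the count floor of 500 is a compromise, not a cliff.
* Step 1 of the two-step fit runs on binned data; fitting raw decays there
  would be marginally cheaper but noisier, and the package does not offer
  it.
* Whether the outlier quartiles should be computed per image or per mask is
  a judgement call; the package computes them in-mask (the conservative
  choice for masked acquisitions) and exposes the mask argument.
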