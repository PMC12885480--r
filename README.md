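# flimpipe

Voxelwise metabolic imaging from NAD(P)H fluorescence lifetime data.

Fluorescence lifetime imaging (FLIM) of the autofluorescent coenzymes
NADH/NADPH — collectively NAD(P)H — resolves the balance between free and
protein-bound coenzyme pools, a label-free readout of cellular energy
metabolism: a higher free fraction indicates a higher glycolysis-to-OXPHOS
ratio. `flimpipe` is an R package for analysing time-correlated single
photon counting (TCSPC) FLIM stacks of the kind produced by in vivo
two-photon microscopy of small-animal brains: it turns 4D photon-count
histograms into per-voxel maps of the free NAD(P)H fraction and bound
lifetime, and those maps into per-subject and group-level statistics. It is
aimed at microscopists and image analysts who need a tested, scriptable
alternative to vendor FLIM software for decay fitting and region
statistics.

## The model

Each voxel's decay is modelled as a two-pool mixture

    d(t) = f_free exp(-t / tau_free) + (1 - f_free) exp(-t / tau_bound)

with `tau_free` fixed at 0.4 ns, convolved with the instrument response
function (IRF) under periodic excitation (laser period T = 12.5 ns,
including the decay remaining from the previous pulse):

    f(t_i) = sum_{p in {0,1}} (d * IRF)(t_i - dt + p T)

The normalised curve plus a constant background b gives per-bin photon
probabilities `s_i`, and parameters are estimated per voxel by minimising
the Poisson deviance

    2I* = 2 sum_i m_i ln( m_i / (C s_i) )

with multi-start Nelder–Mead (5 restarts). Whole images are fitted in two
steps: the time shift `dt` is estimated on a decimated grid, fixed at its
median, and the remaining three parameters are refitted everywhere.
Around the fit sit the processing rules used for in vivo data: exclusion
of abnormally bright voxels (total counts above Q3 + 3 IQR, typically
tracheae), spatial binning with a 21-voxel disk kernel, a 500-photon floor
on binned decays, and post-fit filters `2I* > 200` and `f_free < 0.2`.
Marker-channel segmentation (Li, Otsu, multi-Otsu recipes), subject
summaries, and the usual group tests (pooled and paired t, one-way and
repeated-measures ANOVA, Bonferroni adjustment) complete the pipeline, plus
a simulation that checks whether an observed correlation between fitted
parameters could be a fitting artifact. A synthetic phantom generator with
known ground truth makes the whole chain testable without any data
download.

## Worked example

Fit a single simulated decay (5000 photons, Gaussian IRF) and run the full
pipeline on a two-region phantom:

```r
library(flimpipe)

cfg   <- flim_acquisition()                 # 129 bins over 12.5 ns
irf   <- irf_gaussian()                     # centre 0.5 ns, FWHM 0.2 ns
truth <- decay_params(f_free = 0.7, tau_bound = 3.5)
h     <- sample_decay_counts(truth, irf, cfg, C = 5000, seed = 1)
fit_single_decay(h, irf, cfg, fit_config(rng_seed = 1))
#> flim_fit: 2I* = 90.994 (converged)
#> decay_params: f_free 0.692, tau_free 0.4 ns, tau_bound 3.5 ns, dt -0.00894 ns, b 1.49e-05
```

The fitted free fraction (0.692) and bound lifetime (3.5 ns) recover the
simulated truth to within the noise expected at 5000 photons, and the
deviance (2I\* = 91 over 129 bins) indicates a good fit — well under the
exclusion threshold of 200.

```r
ph  <- generate_phantom(phantom_spec(rng_seed = 1))   # somata 0.68 / calyx 0.75
run <- run_pipeline(ph$flim, ph$marker, irf_gaussian(),
                    recipe  = "mb_cytosolic",
                    regions = ph$masks[c("somata", "calyx")],
                    fit_cfg = fit_config(rng_seed = 2))
run$summaries[, c("region", "mean", "n_voxels", "mean_tau_bound")]
#>   region      mean n_voxels mean_tau_bound
#> 1 somata 0.6891970       71       3.689904
#> 2  calyx 0.7523023      106       3.330060
run$exclusions
#>       segmented bright_outliers      low_counts      two_i_star          f_free
#>             215               2               1               0               0
```

The pipeline segments the marker channel, removes the two injected bright
outlier voxels and one low-count voxel, fits the rest, and recovers the
region means (truth: 0.68 and 0.75) and their contrast. Group tests can be
run from raw subject values or directly from published summary statistics:

```r
t_test_summary(15, 0.715, 0.018, 15, 0.701, 0.022)
#> pooled_t: statistic = 1.908, df = (28), p = 0.06676
```

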