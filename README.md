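# sspdim

Automatic selection of the interference-subspace dimension for
subspace-projection denoising of evoked MEG data.

## The problem

Subspace-projection denoisers — signal space projection (SSP) in the spatial
domain and its spectral counterpart (S3P) — remove environmental
interference from MEG recordings by projecting the data onto the orthogonal
complement of an interference subspace estimated from empty-room noise.
Their one critical tuning parameter is the subspace dimension *x*: the
number of leading noise singular vectors removed.  Too few and interference
remains; too many and the evoked neural response itself is projected away.
`sspdim` chooses *x* automatically from the evoked data, replacing the usual
manual inspection of scree plots and averaged waveforms.

For each candidate *x* the package computes two objectives from band-passed
evoked epochs:

* **F_B(x)** — signal distortion: the ratio of baseline-corrected Morlet
  wavelet power in the evoked time–frequency window after vs. before
  denoising (1 = undistorted, 0 = response removed);
* **F_N(x)** — noise suppression: the channel-weighted ratio of total epoch
  power before vs. after denoising, with weights proportional to each
  channel's standard deviation.

After min–max normalizing F_B to [0, 1] and F_N to [0, 2] over the sweep,
the selected dimension maximizes

```
F_all(x) = α · F_B(x) + (1 − α) · tanh(F_N(x)),        α = 0.5 by default
```

where the tanh saturates the noise term so that aggressive projection cannot
mask serious distortion.

The package also ships a synthetic OPM-MEG study (31 radial magnetometers on
a spherical helmet, a 50 nA·m / 10 Hz dipolar burst over 300 one-second
trials, rank-4 far-field interference with trial-coherent spectral lines,
plus an independent empty-room realization) with a spherical-conductor
radial forward model, an equivalent-current-dipole localizer, and the
evaluation metrics PE (peak error), MAE (mean absolute error) and LE
(localization error) against ground truth.  See the vignette
`vignettes/threshold-estimation.Rmd` for the model, assumptions and design
choices.

## Worked example

```r
library(sspdim)

ds  <- simulate_dataset(sim_config(n_trials = 100), seed = 1)
cfg <- run_config(seed = 1)            # 1–40 Hz, sweep x = 1..10, alpha 0.5
res <- run_pipeline(cfg, ds$epochs, ds$emptyroom, truth = ds$truth)
res$trace
#> <objective_trace> SSP sweep over x = 1..10, alpha = 0.5
#>   x     FB    FN FB_norm FN_norm   Fall
#>   1 0.9847 1.301  1.0000  0.0000 0.5000
#>   2 0.9796 1.567  0.9684  0.4713 0.7038
#>   3 0.9756 1.934  0.9438  1.1220 0.8760
#>   4 0.9682 2.074  0.8974  1.3712 0.8882
#>   5 0.8880 2.273  0.3995  1.7235 0.6689
#>  ...
#> selected x = 4
res$metrics
#> <metrics_report> SSP x=4: PE 46.91 fT, MAE 24.45 fT, LE 1.00 mm
```

The sweep selects x = 4 — the true rank of the simulated interference.  F_B
stays near 1 up to x = 4 and drops sharply beyond it (the evoked response
starts being projected away), while F_N keeps growing slowly; their weighted
sum peaks at the true dimension.  At the selected threshold the denoised
average waveform deviates from the clean simulated signal by ~47 fT at the
response peaks (a few percent of the ~1400 fT peak field), ~24 fT over the
whole epoch, and the fitted dipole lands 1 mm from the true source.

A thin command-line front end over the same functions is installed at
`inst/cli/sspdim-cli.R` with subcommands `simulate`, `estimate-threshold`,
`denoise`, `evaluate` and `run`, using a plain-text fixture format for
recordings (see `?read_recording`).

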