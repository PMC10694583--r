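# phasorflim

Phasor analysis of fluorescence lifetime imaging microscopy (FLIM) data
in R: from per-pixel photon-decay histograms (or vendor phase/modulation
rasters) to calibrated phasor clouds, density-based ROI detection,
lifetime maps, multicomponent unmixing, NADH free/bound metabolic
fractions, and distribution-level statistics.

It is written for microscopists and image analysts who acquire
frequency-domain or time-binned FLIM data and want a scriptable,
reproducible alternative to notebook- or GUI-driven phasor tools: every
step is a documented function, every run is seeded and logged, and all
results land in plain CSV/TIFF files.

## The method in brief

Each pixel's decay $I(t)$ is mapped to its first-harmonic Fourier
coordinates

$$g = \frac{\int_0^T I(t)\cos(n\omega t)\,dt}{\int_0^T I(t)\,dt},\qquad
  s = \frac{\int_0^T I(t)\sin(n\omega t)\,dt}{\int_0^T I(t)\,dt},$$

so monoexponential decays land on the universal semicircle
(centre (1/2, 0), radius 1/2) at $g = 1/(1+(\omega\tau)^2)$, and
mixtures fall inside it at intensity-weighted combinations of the pure
phasors. Per-pixel lifetimes follow from phase and modulation,
$\tau_\varphi = \tan(\varphi)/\omega$ and
$\tau_m = \sqrt{1/m^2 - 1}/\omega$. On top of this the package
implements:

* **calibration** against a known monoexponential reference
  (e.g. fluorescein, 4.0 ns);
* **pixel selection** by custom/Otsu/multi-Otsu thresholds and TIFF
  masks, plus masked 3×3 median or Gaussian filtering of the *g*/*s*
  rasters;
* **level-set contour analysis** of the 100×100 phasor histogram:
  marching-squares contours through a grid of frequency levels yield
  ROI perimeters (≥ 5000 points) with nested phasor cores (≥ 500
  points);
* **unmixing**: two-component (segment projection) and three-component
  (barycentric) fractional intensities, converted to molar fractions
  through brightness ε·QY;
* **metabolic fitting**: a total-least-squares line anchored at the
  free-NADH phasor (0.37 ns) whose second semicircle intersection gives
  the bound-NADH lifetime and per-pixel bound fractions;
* **statistics**: Gaussian-mixture clustering, KS + Mann–Whitney U
  comparison with Bonferroni correction, Gaussian-kernel density
  estimates, and linear/power-law/exponential-rate trend fits.

## Worked example

Simulate a two-population image (1 ns and 4 ns discs on a dark
background, Poisson noise, 500 photons/pixel), transform it, and run
the single-image analysis (contour criteria scaled to the ~500-pixel
discs of this small fixture):

```r
library(phasorflim)

pr    <- acquisition_params(rep_rate = 80e6, harmonic = 1)
sim   <- make_decay_stack(tau_ns = c(1, 4), photons_per_pixel = 500,
                          noise = "poisson", shape = c(64, 64),
                          layout = "two_blobs", n_bins = 256,
                          params = pr, seed = 7)
field <- phasor_field(sim$stack)
cfg   <- run_config(threshold = threshold_spec("custom", custom_value = 0.05),
                    min_roi_points = 200, min_phasor_points = 50, seed = 7)
res   <- analyze_field(field, cfg, sample = "demo", replica = 1)
res
#> FLIM analysis: 1036 retained pixels, 2 ROI(s), 2 phasor(s), 2 cluster(s)
res$df[, c("phasor", "roi", "n_points", "g", "s",
           "tau_phase", "tau_mod", "pca_ratio")]
#>   phasor roi n_points     g     s tau_phase tau_mod pca_ratio
#> 1      1   1       45 0.186 0.397      4.26    4.08     0.565
#> 2      2   2      387 0.798 0.401      1.00    1.00     0.688
```

Two ROIs are found in the phasor plot; their dense cores sit on the
semicircle near the generating lifetimes — the 1-ns disc recovers
τ<sub>φ</sub> = τ<sub>m</sub> = 1.00 ns and the 4-ns disc ≈ 4.1 ns
(Poisson noise plus the coarse phasor-core statistics account for the
spread; `sd_phase`/`sd_mod` in `res$df` quantify it). `export_tables()`
writes the per-pixel `df_dataset.csv` and per-phasor `df.csv`;
`run_pipeline()` does all of the above for batches of files, including
cumulative pooling of replicas named `date_sample name_replica`.

A shell front end with subcommands `simulate`, `analyze`, `compare`,
`unmix` and `nadh` lives in `inst/cli/phasorflim.R`:

```sh
Rscript inst/cli/phasorflim.R simulate --out demo --seed 3 --shape 32
Rscript inst/cli/phasorflim.R analyze --in "demo/*.flim" --out demo_out \
    --threshold 0.05 --min-roi 60 --min-phasor 20 --mode cumulative
```

See `vignettes/phasor-flim-methods.Rmd` for the model, the parameter
conventions, and the design decisions behind each module.

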