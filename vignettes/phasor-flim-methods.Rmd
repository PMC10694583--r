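---
title: "Phasor-FLIM analysis with phasorflim: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-FLIM analysis with phasorflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorflim)
```

## The phasor representation

Fluorescence lifetime imaging microscopy (FLIM) records, in every pixel,
how the fluorescence intensity $I(t)$ decays after pulsed excitation.
Instead of fitting multiexponential models pixel by pixel, the phasor
approach maps each decay to its normalised first-harmonic Fourier
coordinates

$$
g = \frac{\int_0^T I(t)\cos(n\omega t)\,dt}{\int_0^T I(t)\,dt},
\qquad
s = \frac{\int_0^T I(t)\sin(n\omega t)\,dt}{\int_0^T I(t)\,dt},
$$

with $T$ the laser period, $n$ the harmonic and
$\omega = 2\pi n / T$. Equivalently $g = m\cos\varphi$,
$s = m\sin\varphi$ with modulation $m$ and phase $\varphi$. A
monoexponential decay with lifetime $\tau$ lands on the *universal
semicircle* of centre $(\tfrac12, 0)$ and radius $\tfrac12$ at
$g = 1/(1+(\omega\tau)^2)$, $s = \omega\tau/(1+(\omega\tau)^2)$;
mixtures fall inside the semicircle at the fractional-intensity-weighted
combination of the component phasors. Two lifetime estimates follow per
pixel,

$$
\tau_\varphi = \frac{1}{\omega}\tan\varphi, \qquad
\tau_m = \frac{1}{\omega}\sqrt{\frac{1}{m^2} - 1},
$$

which agree exactly for monoexponential decays and split apart for
mixtures — itself a useful diagnostic.

`phasor_of_decay()` evaluates the integrals by the rectangle rule at the
bin centres of the photon histogram. The synthetic generator produces
*period-wrapped* decays (the steady-state shape under periodic
excitation), for which the continuous-limit phasor equals the closed
form above; this makes the closed form a legitimate independent oracle
for the discrete transform. The wrapped exponential has a jump at
$t = 0$, so the rectangle-rule error decreases only linearly with the
bin width; 1024 bins keep lifetime errors below $10^{-4}$ ns at 80 MHz,
and the transform-accuracy tests use 2048 bins where they assert
$10^{-4}$ agreement on $g$ and $s$ across $\omega\tau \in [0.01, 100]$.

```{r}
pr <- acquisition_params(rep_rate = 80e6, harmonic = 1)
phasor_mono(4, pr)   # the 4.0-ns fluorescein reference at 80 MHz
```

## Calibration

Frequency-domain instruments add a phase offset and a modulation scaling
to every pixel. Both are estimated from a reference measurement of a
fluorophore with known monoexponential lifetime — classically
fluorescein at pH 11 (4.0 ns) — by `fit_calibration()`, and removed per
pixel by `apply_calibration()` ($m \mapsto m \cdot k$,
$\varphi \mapsto \varphi + \Delta\varphi$). One correction applies per
acquisition session, not per pixel. The pipeline applies calibration to
the raw rasters *before* spatial filtering; the alternative order is
possible by calling the functions directly.

## Preprocessing: thresholding and masked filtering

Intensity is normalised to $[0,1]$ before thresholding
(`normalize_intensity()`), so custom thresholds are scale-free. Three
threshold methods are available (`threshold_spec()`): a custom value,
two-class Otsu (computed on a 256-level histogram via EBImage), and the
default three-class multi-Otsu, where pixels above the *lowest* class
boundary are kept. The lowest boundary is the permissive reading of
"relevant pixels" — it keeps both intermediate and bright classes — and
is the configurable default. With an imported mask the recommended
threshold is 0, so the mask alone delimits the analysis.

Spatial filtering (`smooth_phasors()`, default 3×3 median, common
practice in phasor FLIM) operates on the $g$ and $s$ rasters rather
than on phase and modulation: filtering the angle would wrap at
$\pm\pi$, while $g/s$ filtering is wrap-safe. Only valid, selected
pixels enter a window — invalid neighbours are excluded rather than
imputed — and windows are clipped at image borders so no edge values
are invented. Filtering changes values, never membership: the retained
pixel set is fixed by thresholding alone. These masked-window filters
are implemented in compiled code under `src/`.

## Level-set contour analysis of the phasor histogram

Retained pixels are binned into a 2D histogram (default 100 bins per
axis over $g \in [0,1]$, $s \in [0, 0.6]$ — the semicircle bounding box
with headroom; the axis limits are configurable because real clouds can
sit anywhere inside it). The histogram is treated as a count surface
and scanned through a fixed grid of `n_levels` (default 10) linearly
spaced frequency levels between a *bottom* level — by default the
smallest nonzero bin count, i.e. the floor attainable after intensity
thresholding — and a *top* level, by default the 95th percentile of
nonzero bin counts. Both can be overridden to suppress frequency noise;
a fixed level grid keeps the procedure deterministic and tunable.

At each level, closed iso-count contours are extracted by marching
squares (`grDevices::contourLines`). The surface is padded with a
below-bottom ring first, which closes boundary-touching contours along
the histogram edge. Each contour polygon is assigned a *point count* —
the sum of counts of bins whose centres it contains — and classified:

* disjoint from every stored ROI perimeter and holding at least
  `min_roi_points` (default 5000) points: a new ROI, which also seeds
  its first nested phasor;
* contained in a stored perimeter and in one of its stored phasors:
  *replaces* the innermost containing phasor, refining it toward the
  density mode as the level rises;
* contained in a perimeter but in no stored phasor, with at least
  `min_phasor_points` (default 500) points: a new phasor, capturing a
  secondary mode.

Only the final polygon of each phasor is kept; the number of
refinements is logged as `depth`. Refinement stops once the candidate
core would drop below `min_phasor_points` — near the mode the top-level
contour can shrink below a single histogram bin, and an (almost) empty
polygon is not a usable phasor — so every reported phasor honours the
same validity criterion as a newly created one. Containment is decided by a
representative interior point plus an area comparison, which is robust
to marching-squares vertex jitter where strict vertex-wise inclusion is
not. If no contour reaches `min_roi_points` the result is an empty
region set with a warning, not an error, so batch runs continue.

The point-count definition is validated in the tests against direct
point-in-polygon counting of the raw $(g, s)$ points; the two agree up
to the counts in the one-bin ring straddling the polygon boundary,
which is the exact quantisation limit of bin-centre counting.

## Lifetime metrics and ROI summaries

`summarize_phasor()` reports the barycenter, the intensity-weighted
barycenter, standard errors, and a principal-component variability
ratio defined as $\lambda_1 / (\lambda_1 + \lambda_2)$ of the $(g,s)$
covariance — 0.5 for an isotropic blob, 1 for a perfectly directional
(line-like) phasor. The ratio of eigenvalues $\lambda_1/\lambda_2$ is
an equally defensible convention; the share form was chosen because it
is bounded in $[0.5, 1]$ and therefore directly comparable across ROIs.
Lifetime maps use $\tau_m$ by default (`type = "phase"` switches), and
ROI standard deviations are computed over pixels; per-replica
aggregation is available downstream of the exported tables.

## Multicomponent unmixing and molar fractions

Two-species mixtures lie on the segment between the pure phasors:
`fractions_two()` projects the observed point orthogonally onto the
segment and reads the fractional intensity off the projection
parameter. Three-species mixtures fill the triangle of the pure
phasors: `fractions_three()` solves the barycentric system
$[g; s; 1] = M f$ exactly. Points pushed outside the gamut by noise are
clipped and renormalised with `in_gamut = FALSE` rather than rejected,
because small excursions are routine in measured data; the
perpendicular tolerance of the two-species gamut check defaults to 0.05
phasor units, about twice the cloud spread of a moderate-photon-count
measurement.

Fractional intensities weight species by brightness
$B = \varepsilon \cdot QY$; `molar_from_intensity()` converts to molar
fractions via $x_i \propto f_i / B_i$. Pure-species phasors default to
the closed form at the species lifetime, with measured overrides
available in the species table, since environment and encapsulation
shift real reference phasors off the ideal position.

```{r}
crystal <- flim_species("crystal", 0.8, epsilon = 1.0, qy = 0.9, params = pr)
free    <- flim_species("free",    1.9, epsilon = 1.0, qy = 0.1, params = pr)
mid <- phasor_point((crystal$phasor$g + free$phasor$g) / 2,
                    (crystal$phasor$s + free$phasor$s) / 2)
molar_from_intensity(fractions_two(mid, crystal, free), list(crystal, free))
```

## The free/bound NADH metabolic fit

Cellular NAD(P)H phasors are modelled as mixtures of free NADH — a
fixed semicircle vertex at the literature lifetime of 0.37 ns — and
enzyme-bound NADH, whose lifetime varies between roughly 1 and 9 ns
with the binding enzyme. `nadh_bound_fit()` fits a line through the
fixed free vertex by constrained total least squares: the direction is
the principal eigenvector of the point scatter about the vertex, which
minimises summed perpendicular distances and treats $g$ and $s$
symmetrically (an ordinary regression of $s$ on $g$ would not). The
bound-state phasor is the line's second intersection with the
semicircle — the root with smaller $g$, i.e. the longer lifetime, since
bound NADH is the long-lived state — and each point's bound fraction is
its two-component fraction along the free–bound segment. Lifetimes
outside $[1, 9]$ ns warn but do not fail; a line that misses the
semicircle or a cloud degenerate at the free vertex is an error that
points the user back at thresholding and filtering.

## Clustering, distribution comparison and trends

`fit_gmm()` clusters phasor clouds (or lifetime vectors) with a
full-covariance Gaussian mixture, the natural model given the normal
noise component of phasor distributions; the default is two clusters.
The fit uses mclust, whose model-based agglomerative initialisation is
deterministic for a given data set — repeated runs are bitwise
identical, which the tests assert; a seed argument is still recorded
for provenance. Degenerate inputs (zero spread) return a
variance-floored single-component model instead of crashing.

`compare_distributions()` applies the two standard nonparametric
two-sample tests — Kolmogorov–Smirnov and Mann–Whitney U, two-sided —
with Bonferroni correction. The multiplicity defaults to $m = 2$, the
two statistics computed in one call; studies comparing several sample
pairs should raise `n_tests` accordingly. Small tie-free samples get
the exact Mann–Whitney distribution, larger ones the tie-corrected
normal approximation. Kernel density estimates use a Gaussian kernel
with a 0.01-ns default bandwidth on a common grid, alongside
percentile, skewness and spread summaries. Under the null, the
union-of-two-tests rejection rate at $\alpha = 0.05$ after Bonferroni
is bounded by 0.05 and bounded below by each test's share; the test
suite verifies an empirical rate in $[0.01, 0.09]$ over 1000
simulations.

`fit_trend()` covers the three trend models that recur in lifetime
studies: ordinary least squares, a power law fitted on the log–log
scale (stable, linear, and exactly testable; a direct nonlinear fit of
$y = ax^b$ would weight residuals differently), and a monoexponential
relaxation $y = c + a e^{-t/\tau_d}$ for inverse-lifetime decay over
storage time, fitted by Levenberg–Marquardt nonlinear least squares
with data-driven starting values. $R^2$ is always reported on the
fitted scale.

## Synthetic data: what it does and does not emulate

`make_decay_stack()` generates period-wrapped mixtures of
monoexponential decays with optional Poisson (shot) noise, in uniform,
checkerboard or two-blob layouts, together with closed-form ground
truth per pixel; `make_phasor_cloud()` generates labelled Gaussian
clusters directly in phasor space. Defaults mirror a typical
two-photon acquisition: 80 MHz repetition rate, harmonic 1, 256 time
bins. The generators are seed-deterministic and reproduce the phasor
geometry (semicircle for pure species, interior for mixtures) exactly
in expectation.

They deliberately do not simulate instrument response functions,
digital-frequency-domain electronics, detector afterpulsing, or
autofluorescence backgrounds. Passing tests therefore demonstrate the
correctness of the computations under idealised photon statistics, not
robustness to every instrument artefact; calibration against a measured
reference remains the user's responsibility on real data.

Test problem sizes are chosen to exercise the defaults at desk scale:
clouds of 6000–10000 points against the 5000-point ROI criterion,
32–64 pixel images for pipeline runs, 1000 null replicates for the
type-I-error check.

## File formats and degenerate inputs

The package defines a documented single-file binary container (magic
header, JSON metadata, float64 planes) for decay stacks and
multi-harmonic phasor rasters, and a best-effort reader for the
SimFCS-style `.ref` dialect under explicit, overridable assumptions:
row-major float32 planes ordered intensity, then phase/modulation per
harmonic, phase in degrees, default 256×256. None of these assumptions
is vendor-documented, so each is an argument. `.R64` and `.ifli` are
compressed or undocumented vendor layouts; `register_flim_reader()`
lets users plug in a decoder, and the built-in stub fails with a clear
message. Masks are 8-bit single-plane TIFFs (nonzero = keep); maps are
written as float32 TIFFs with `-1` as the documented absent-value
sentinel.

Degenerate inputs follow one rule: per-pixel problems (zero photons,
$g \le 0$, $m > 1$) flag the pixel and continue; whole-analysis
problems (empty selection, empty histogram, coincident species,
degenerate reference) raise errors naming the cause; and batch runs
skip unreadable files, failing only when every input fails.

## Known limitations

* Single-harmonic analysis only; resolving more than three components
  requires multi-harmonic data, which is out of scope.
* No time-domain instrument-response deconvolution and no per-pixel
  multiexponential curve fitting — the phasor representation is the
  analysis substrate.
* The `.ref` dialect assumptions must be validated against files from
  the user's own instrument.
* Deep-learning segmentation is not bundled; external masks serve that
  role through the TIFF import hook.
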