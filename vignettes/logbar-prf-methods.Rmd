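---
title: "Log-bar pRF mapping: model, fitting, and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-bar pRF mapping: model, fitting, and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logprf)
```

## The problem

Population receptive field (pRF) mapping estimates, for every voxel or
surface vertex in visual cortex, the region of visual space driving its
BOLD response, modelled here as an isometric 2-D Gaussian with center
$(\mu_x, \mu_y)$ and size $\sigma$ in degrees of visual angle. The
standard stimulus is a bar of fixed width (2°) drifting at fixed speed
(0.4°/s) behind a circular aperture (radius $r_{max} = 8$°). Because
cortical magnification concentrates most of early visual cortex on the
fovea — and pRF sizes there are on the order of 0.1° — a fixed 2° bar is
both far too wide and effectively far too fast for foveal pRFs: their
responses are dominated by the bar's geometry rather than their own, and
size and eccentricity estimates are biased upward.

The log-bar stimulus addresses this by warping every frame of the
fixed-bar movie along the eccentricity axis with

$$ r' = c \cdot \log(1 + k \, r), \qquad c = \frac{r_{max}}{\log(1 + k\,r_{max})}, $$

using the natural logarithm and $k = 5$, a distortion roughly matched to
the cortical magnification of human early visual cortex. The choice of
$c$ pins the aperture edge: `log_map(8) = 8`. As $k \to 0$ the warp tends
to the identity; below $k = 10^{-6}$ the implementation returns the
identity exactly to avoid cancellation in $c$.

### Which way the warp is applied

The warp is stated as a mapping of eccentricities, which leaves the
sampling direction of the image transform ambiguous. This package
resolves it physically. The output (log-bar) pixel at polar coordinates
$(\theta, r)$ displays the fixed-bar content at $(\theta, c\log(1+kr))$;
equivalently, a fixed-space feature at eccentricity $\rho$ appears in the
log-bar frame at the *inverse* warp of $\rho$. With this convention a bar
whose fixed-space center sweeps at constant speed $v$ follows
$r(t) = (e^{vt/c} - 1)/k$ in the log-bar movie, and its position on a
log-mapped cortical surface, $\log(1 + k\,r(t))$, advances exactly
linearly in time. It also yields the qualitative signature of the
stimulus: a thin, slow bar near the fovea and a wide, fast bar in the
periphery (a fixed bar occupying 0–2° appears at 0–0.31°; one at 6–8°
appears at 3.04–8°). The opposite sampling direction produces a bar that
is widest at the fovea and decelerates on cortex, contradicting both the
stimulus' purpose and its appearance, so it is not used.

The warp is applied frame-by-frame to the rendered fixed-bar movie
(including diagonal sweeps) by backward mapping with bilinear
interpolation, then re-thresholded at 0.5 to restore a binary mask —
backward sampling avoids the holes a forward scatter would create.

## Stimulus construction

A run is a 2 s blank, eight 45 s sweeps, and a 4 s blank: 366 s. Each
sweep traverses 18° (the 16° aperture diameter plus one bar width), so
`speed * duration = 2 rmax + bar_width` exactly at the defaults. The
direction set — not stated by the source protocol beyond "pseudorandomly
chosen" — defaults to 8 directions at 45° increments (4 orientations × 2
senses), one of each per run, shuffled by a seed; both the set and the
order are configurable. Frames are sampled at frame centers
$(i - \tfrac12)/\mathrm{fps}$.

Movies are rendered at 540 × 540 px (configurable; the `fast` simulation
profile renders at 216 px, which after downsampling to the common
108 px fitting resolution is pixel-wise very close), binarized, spatially
downsampled by block averaging (or separable linear interpolation for
non-divisible targets), temporally downsampled by linear interpolation to
366 frames, and re-thresholded at 0.5. Whether the original analysis
re-binarized after downsampling or kept fractional coverage is unstated;
re-binarization is the default and `binarize = FALSE` keeps fractional
coverage. The native render frame rate (also unstated) defaults to 10 fps
at full scale and 2 fps in the fast profile; since the bar moves 0.4°/s,
even 1 fps steps the bar by less than half a bar width per frame.

## Forward model

The predicted response is the spatial dot product of the stimulus frame
with the Gaussian weight image, convolved with a hemodynamic response
function (HRF):

$$ \hat R(t) = \Big[\textstyle\sum_{x,y} S(x,y,t)\,G(x,y)\Big] \circledast h(t). $$

$G$ uses unit peak rather than unit volume: the fit objective is a
Pearson correlation, which is invariant to affine scaling, so the
normalization (and any amplitude or baseline parameter) is irrelevant and
none is fit.

The HRF is the standard double-gamma — a difference of two gamma
densities with the undershoot scaled by $1/\mathrm{ratio}$, delayed by
$\delta$, six parameters in all. The displayed source expression has
positive exponentials and omits the ratio; taken literally it diverges,
so the package implements the SPM form the text attributes it to.
Because the printed parameter glosses ("time to peak", "dispersion")
also suggest a peak-time parameterization, both are exposed:
`hrf_params()` (shape/rate) and `hrf_params_peaktime()` with converters,
related by $\alpha = \mathrm{peak}/\mathrm{disp}$,
$\beta = 1/\mathrm{disp}$. Defaults are the SPM canonical values
($\delta = 0$, shapes 6 and 16, rates 1 and 1, ratio 6; positive lobe
peaks at $(\alpha_1 - 1)/\beta_1 = 5$ s). Convolution is causal,
discrete, truncated to the input length, with a 40 s kernel support.

## Fitting

Fitting is two-stage and deterministic. A coarse grid search evaluates
every seed — centers from −8° to 8° in 20 steps per axis, sizes 1–5° in
20 steps, 8000 seeds at the defaults (the size seeds deliberately start
above expected pRF sizes; convergence is steeper from above) — and the
argmax (ties to the lowest index) seeds a Nelder–Mead simplex over
$(\mu_x, \mu_y, \log\sigma)$ minimizing the negative correlation. The
log parameterization enforces $\sigma > 0$; the returned fit never
scores below its seed. Stopping uses a relative objective tolerance of
$10^{-8}$ and at most 600 iterations — tighter than classical
`fminsearch` tolerances because each objective evaluation here costs
well under a millisecond, and the tighter stop measurably removes a
small optimizer-induced bias for pRFs near the bar-width information
limit.

The HRF is estimated by coordinate ascent: hold the grid-search pRFs
fixed, fit the six HRF parameters per selected unit (simplex on
$(\delta, \log\alpha_1, \log\alpha_2, \log\beta_1, \log\beta_2,
\log\mathrm{ratio})$), take the element-wise median across units, and
repeat for three iterations before a final grid search plus refinement.
To bound computation only 15% of the units with variance explained
above 20% are fit; *which* 15% is not stated in the source, so the
package takes the top 15% by variance explained — a deterministic choice
that favours the best-constrained units. Fits are retained iff
eccentricity < 8°, $\sigma$ > 0.05°, and variance explained > 10%
(strict inequalities, as printed).

Zero-variance time courses (or degenerate predictions) yield `NA`
correlations and are flagged unretained rather than raising errors, so
batch fits never abort.

## Simulation: the stated world

The ground-truth grid crosses 24 polar angles (0–345° in 15° steps) with
200 log-spaced eccentricities (0.01–8°): 4800 pRFs, sizes from
$\sigma = 0.15\,\mathrm{ecc} + 0.1$. Noiseless time courses come from
the same forward model used in fitting; IID Gaussian noise is added and
the grid is replicated (100 times at full scale).

The source matched the noise standard deviation to the average variance
of its fMRI data without printing a value. To keep the experiment
self-contained the noise level is stated as a per-unit time-course SNR:
each noiseless prediction is peak-normalized and noise with
$\mathrm{sd} = \mathrm{peak}/\mathrm{SNR}$, $\mathrm{SNR} = 3$, is
added. Peak normalization reflects that BOLD percent-signal change is
broadly comparable across voxels rather than scaling with pRF overlap
area; a single unnormalized sd would instead drown every small-σ foveal
unit in noise for *both* stimulus types. SNR = 3 is a mid-range value
for single-run visual-cortex time series; it was chosen once, before any
recovery numbers were inspected, and is configurable (`noise_spec(sd=)`
overrides it).

The full-scale experiment (4800 × 100 × 2 stimuli through an 8000-seed
search) is not a desk-scale computation, so the packaged `fast` profile
scales it down — 45° angle steps, 50 eccentricity steps, 10 replicates,
a 10 × 10 × 10 seed grid, 216 px render — while keeping the 108 × 108 ×
366 fitting resolution and every other stated parameter. The recovery
experiment fits with the same (known) HRF that generated the data;
`fit_hrf = TRUE` enables the alternating estimation instead, at
substantial cost and with no change to the generating model.

What a green recovery test establishes: that under IID noise at the
stated SNR the fixed-bar stimulus overestimates small foveal sizes and
the log-bar does not, and that the log-bar's recovered sizes track truth
across eccentricity. What it does not establish: behaviour under
spatially or temporally correlated physiological noise, hemodynamic
variability across units, nonlinear (compressive) spatial or temporal
summation, or measurement confounds — none of which are modelled, by
design. The linear model itself is known to overestimate sizes where
real cortex is subadditive.

One internal inconsistency of the source is left visible rather than
resolved: it states fixed-bar overestimation for true sizes < 0.2°,
"representing" eccentricities < 1.5°, but the printed size relation
gives $\sigma(1.5°) = 0.325°$. The recovery report therefore bins the
full eccentricity range instead of hard-coding either threshold; the
acceptance check uses the eccentricity form (< 1.5°).

## Reliability metrics

Session-to-session reliability uses Spearman rank correlation (midrank
ties) for eccentricity and size, and a circular correlation for polar
angle. The source does not name its circular coefficient; the package
uses the Fisher–Lee pairwise definition (rotation-invariant,
$O(n^2)$ pairs) and documents it as a swappable choice. Correlations are
reported alongside Fisher z ($\mathrm{atanh}$); $|r| = 1$ yields
$\pm\infty$ with a warning rather than silent clipping. Behavioral
performance on the fixation task is
$(n_{hit} - n_{fa})/n_{total} \times 100$.

## Numerical and interface choices

* Pixel centers at half-integer offsets; x rightward, y upward, origin at
  fixation; polar angle counter-clockwise from +x.
* Binarization threshold 0.5 everywhere a mask is restored.
* The fitting inner loop runs over a run-length encoding of the binary
  aperture (bar ∩ disc columns are short row intervals), with the
  Gaussian row-sums taken from prefix sums; it is exact to rounding and
  verified against a per-pixel brute-force oracle at $10^{-10}$.
  During fitting the Gaussian is truncated at 8σ (error < 1e−11 of the
  overlap); public predictions are untruncated.
* Movies and fit tables are exchanged as TSV/JSON sidecar and RDS; no
  NIfTI-capable R package is assumed in the runtime environment, so
  NIfTI import/export is out of scope (the calibration metadata a NIfTI
  header would carry lives in the JSON sidecar).
* All randomness (sweep order, noise) is seeded; identical configs give
  bit-identical outputs.

## Worked example

```{r example, eval = FALSE}
library(logprf)

# a fast-profile recovery experiment (about two minutes)
ex <- recovery_experiment(seed = 1, profile = "fast")
subset(ex$report, ecc_hi < 1.6)[, c("label", "ecc_lo", "ecc_hi",
                                    "truth_sigma", "est_sigma", "bias")]

# warp geometry
ws <- warp_spec(k = 5, rmax = 8)
log_map(c(0, 2, 8), ws)        # 0.000 5.166 8.000
inverse_log_map(2, ws)         # 0.306: where a 2-deg feature appears
```

## Known limitations

* The simulation's noise model is IID Gaussian at a stated SNR; absolute
  bias magnitudes (not their ordering) depend on that choice.
* The alternating HRF fit assumes a single HRF per labelled group of
  units; per-unit hemodynamic variability is not modelled.
* The Gaussian pRF is linear and isometric: no compressive summation,
  surround suppression, or elliptical fields.
* `circular_cor()` is $O(n^2)$ in pairs; for very large vertex counts
  subsample or replace the coefficient.
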