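# logprf

Population receptive field (pRF) mapping with a logarithmically warped
drifting-bar stimulus, in R.

## The problem

pRF mapping estimates, for each voxel or surface vertex of visual
cortex, the 2-D Gaussian region of visual space — center (μx, μy),
size σ, in degrees of visual angle — whose overlap with the stimulus,
convolved with a hemodynamic response function (HRF), best predicts the
measured BOLD time course:

    R̂(t) = [ Σ_xy S(x,y,t) · G(x,y; μx, μy, σ) ] ⊛ h(t)

A bar of fixed width (2°) and speed (0.4°/s) is the standard mapping
stimulus, but cortical magnification makes it a poor probe of the fovea,
where pRFs are ~0.1° wide: foveal size and eccentricity estimates are
biased upward. The **log-bar** stimulus warps every frame of the
fixed-bar movie along the eccentricity axis,

    r' = c·log(1 + k·r),   c = rmax / log(1 + k·rmax),   k = 5, rmax = 8,

so the bar is thin and slow near the fovea and wide and fast in the
periphery — approximately a constant-width, constant-speed bar on the
cortical surface. This package implements the full method: stimulus
generation and warping, the Gaussian-pRF forward model with a
six-parameter double-gamma HRF, two-stage fitting (exhaustive grid
search + Nelder–Mead refinement of the correlation objective, with
alternating HRF estimation and retention filtering), reliability
metrics, and the parameter-recovery simulation that quantifies the
log-bar's accuracy advantage. It is aimed at visual neuroscientists
designing retinotopy protocols and at methodologists studying pRF
estimator bias.

## Worked example

```r
library(logprf)

ws <- warp_spec(k = 5, rmax = 8)
log_map(c(0, 2, 8), ws)
#> [1] 0.00000 5.16569 8.00000     # edge pinned: log_map(8) = 8
inverse_log_map(2, ws)
#> [1] 0.3060879                   # a 2-deg feature appears at 0.31 deg

# desk-scale parameter-recovery experiment (~2-3 min):
# 8 angles x 50 eccentricities, 10 noisy replicates, both stimulus types
ex <- recovery_experiment(seed = 1, profile = "fast")
ex$report[c(1, 2, 17, 18),
          c("label", "ecc_lo", "ecc_hi", "truth_sigma", "est_sigma", "bias")]
#>    label ecc_lo ecc_hi truth_sigma est_sigma    bias
#> 1  fixed 0.0100 0.0152       0.102     0.324 0.22204
#> 2  fixed 0.0152 0.0231       0.103     0.317 0.21452
#> 17   log 0.0100 0.0152       0.102     0.109 0.00737
#> 18   log 0.0152 0.0231       0.103     0.106 0.00278
```

The bias column is mean(estimated σ − true σ) over retained fits per
eccentricity bin: the fixed bar overestimates foveal pRF size roughly
threefold (σ̂ ≈ 0.32° against a truth of ~0.10°), while the log-bar
recovers it to within a few thousandths of a degree. Averaged over all
ground-truth eccentricities below 1.5°, the fixed-bar size bias is
+0.193° against +0.002° for the log-bar. Beyond ~1.5° eccentricity the
two stimuli perform similarly.

Fitting a time-course matrix directly:

```r
fits <- fit_prfs(tc_matrix, stim, hrf_params())   # one row per unit
subset(fits, retained)[, c("mu_x", "mu_y", "sigma", "variance_explained")]
```

## Command line

```sh
Rscript inst/cli/logprf.R stimulus --mode log --k 5 --rmax 8 --seed 1 --out movie.rds
Rscript inst/cli/logprf.R simulate --profile fast --seed 1 --out simdir/
Rscript inst/cli/logprf.R fit --stim movie.rds --data tc.tsv --out fits.tsv
Rscript inst/cli/logprf.R report --fits-a s1.tsv --fits-b s2.tsv --out rel.tsv
```

## Layout

- `R/`, `src/` — implementation (stimulus, hemodynamics, forward model,
  fitting, simulation, metrics, config/CLI; Rcpp inner loop).
- `tests/testthat/` — unit, property, and acceptance tests
  (`test-acceptance.R` holds the acceptance criteria).
- `vignettes/logbar-prf-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, what the simulation does and does not
  establish.
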