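# Two-stage pRF estimation: exhaustive coarse grid search over seed
# parameters, then derivative-free simplex (Nelder-Mead, fminsearch-like)
# refinement of (mu_x, mu_y, sigma) maximizing the Pearson correlation
# between predicted and observed time courses. sigma is optimized in log
# space to enforce positivity. The correlation objective is invariant to
# affine scaling of the prediction, so no amplitude/baseline is fit.

#' Grid-search seed specification
#'
#' Defaults follow the coarse search used for the two-stage fit: centers
#' linearly sampled from -8 to 8 degrees in 20 steps per axis, sizes
#' linearly spaced from 1 to 5 degrees in 20 steps (8000 seeds). The size
#' seeds deliberately exceed expected pRF sizes: convergence is steeper
#' when starting from above.
#'
#' @param center_min,center_max Center seed range, degrees.
#' @param center_steps Seeds per center axis (>= 2).
#' @param sigma_min,sigma_max Size seed range, degrees.
#' @param sigma_steps Size seeds (>= 2).
#' @return An object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(center_min = -8, center_max = 8,
                             center_steps = 20,
                             sigma_min = 1, sigma_max = 5, sigma_steps = 20) {
  stopifnot(center_steps >= 2, sigma_steps >= 2,
            center_min < center_max, sigma_min < sigma_max, sigma_min > 0)
  structure(list(center_min = center_min, center_max = center_max,
                 center_steps = as.integer(center_steps),
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 sigma_steps = as.integer(sigma_steps)),
            class = "grid_search_spec")
}

#' Seed table of a grid-search specification
#'
#' @param spec A [grid_search_spec()].
#' @return Data frame with columns `mu_x`, `mu_y`, `sigma`, one row per
#'   seed, in a fixed order (`mu_x` varies fastest); ties in the search are
#'   broken toward the lowest row index.
#' @export
grid_seeds <- function(spec) {
  stopifnot(inherits(spec, "grid_search_spec"))
  cx <- seq(spec$center_min, spec$center_max, length.out = spec$center_steps)
  sg <- seq(spec$sigma_min, spec$sigma_max, length.out = spec$sigma_steps)
  expand.grid(mu_x = cx, mu_y = cx, sigma = sg,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Retention rule for fitted pRFs
#'
#' A fit is retained iff eccentricity `< max_ecc`, size `> min_sigma`, and
#' variance explained `> min_ve` (all strict, as stated: within the
#' display, above the size floor, above 10 percent VE).
#'
#' @param max_ecc Maximum center eccentricity, degrees.
#' @param min_sigma Minimum pRF size, degrees.
#' @param min_ve Minimum variance explained, proportion.
#' @return An object of class `retention_rule`.
#' @export
retention_rule <- function(max_ecc = 8, min_sigma = 0.05, min_ve = 0.10) {
  for (nm in c("max_ecc", "min_sigma", "min_ve"))
    .check_num(get(nm), nm, positive = TRUE)
  structure(list(max_ecc = max_ecc, min_sigma = min_sigma, min_ve = min_ve),
            class = "retention_rule")
}

#' Correlation objective
#'
#' Pearson correlation between data and prediction; the quantity maximized
#' by the fit. Zero variance in either input yields `NA` (an invalid fit
#' flag), never an error that would abort a batch.
#'
#' @param data,prediction Equal-length numeric vectors or [timecourse()]s.
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
prf_objective <- function(data, prediction) {
  d <- .tc_values(data); p <- .tc_values(prediction)
  if (length(d) != length(p)) stop("length mismatch", call. = FALSE)
  if (sd(d) == 0 || sd(p) == 0) return(NA_real_)
  cor(d, p)
}

#' Precomputed fitting context
#'
#' Bundles the sparse stimulus representation and the sampled HRF kernel so
#' repeated fits against the same (stimulus, HRF) pair avoid recomputation.
#'
#' @param stim A preprocessed [stimulus_movie()].
#' @param hrf An [hrf_params()] object.
#' @param span HRF kernel support, seconds.
#' @param cutoff_sigmas Gaussian truncation radius in units of sigma used
#'   during fitting (default 8; `Inf` disables truncation). At 8 sigma the
#'   truncation error is below 1e-11 of the overlap and only speeds up the
#'   inner loop.
#' @return An object of class `fit_context`.
#' @export
fit_context <- function(stim, hrf, span = 40, cutoff_sigmas = 8) {
  stopifnot(inherits(stim, "stimulus_movie"), inherits(hrf, "hrf_params"))
  sp <- .stim_sparse(stim)
  structure(list(sp = sp, hrf = hrf, kernel = hrf_kernel(hrf, sp$dt, span),
                 span = span, cutoff = cutoff_sigmas, dt = sp$dt),
            class = "fit_context")
}

.as_ctx <- function(ctx, stim, hrf, span = 40) {
  if (!is.null(ctx)) return(ctx)
  fit_context(stim, hrf, span)
}

# center + scale to unit sum of squares; zero-variance -> NULL
.zscore <- function(d) {
  c0 <- d - mean(d)
  ss <- sqrt(sum(c0^2))
  if (ss == 0) return(NULL)
  c0 / ss
}

# correlations of all (standardized) prediction columns with one
# standardized data vector; zero-variance predictions give NA
.grid_cor <- function(Pz, dz) as.vector(crossprod(Pz, dz))

# standardize prediction matrix columns; zero-variance columns become NA
.standardize_cols <- function(P) {
  Pc <- sweep(P, 2, colMeans(P))
  ss <- sqrt(colSums(Pc^2))
  bad <- ss == 0
  ss[bad] <- 1
  Pz <- sweep(Pc, 2, ss, "/")
  Pz[, bad] <- NA_real_
  Pz
}

#' Coarse grid search for seed pRF parameters
#'
#' Evaluates the correlation objective for every seed in the grid
#' (`center_steps^2 * sigma_steps` candidates; 8000 at the defaults) and
#' returns the argmax. Ties break to the lowest seed index; deterministic.
#'
#' @param data A [timecourse()] or numeric vector.
#' @param stim,hrf Stimulus movie and HRF (ignored when `ctx` is given).
#' @param spec A [grid_search_spec()].
#' @param ctx Optional [fit_context()].
#' @param P Optional precomputed prediction matrix for the seeds (columns
#'   in `grid_seeds(spec)` order), as returned by [grid_predictions()].
#' @return List with `prf` (the best seed as [prf_params()]),
#'   `correlation`, and `index` (row in `grid_seeds(spec)`).
#' @export
grid_search <- function(data, stim = NULL, hrf = NULL,
                        spec = grid_search_spec(), ctx = NULL, P = NULL) {
  ctx <- .as_ctx(ctx, stim, hrf)
  seeds <- grid_seeds(spec)
  if (is.null(P)) P <- grid_predictions(spec, ctx = ctx)
  dz <- .zscore(.tc_values(data))
  if (is.null(dz))
    return(list(prf = NULL, correlation = NA_real_, index = NA_integer_))
  r <- .grid_cor(.standardize_cols(P), dz)
  i <- which.max(r)  # NA columns are never the max; ties -> lowest index
  list(prf = prf_params(seeds$mu_x[i], seeds$mu_y[i], seeds$sigma[i]),
       correlation = r[i], index = i)
}

#' Prediction matrix for all grid seeds
#'
#' @param spec A [grid_search_spec()].
#' @param stim,hrf Stimulus and HRF (ignored when `ctx` given).
#' @param ctx Optional [fit_context()].
#' @return Numeric matrix, one column per row of `grid_seeds(spec)`.
#' @export
grid_predictions <- function(spec, stim = NULL, hrf = NULL, ctx = NULL) {
  ctx <- .as_ctx(ctx, stim, hrf)
  seeds <- grid_seeds(spec)
  .predict_matrix(ctx$sp, seeds$mu_x, seeds$mu_y, seeds$sigma, ctx$kernel,
                  ctx$cutoff)
}

# negative correlation objective over (mu_x, mu_y, log sigma)
.refine_obj <- function(par, ctx, dz) {
  p <- .predict_matrix(ctx$sp, par[1], par[2], exp(par[3]), ctx$kernel,
                       ctx$cutoff)[, 1]
  r <- cpp_cor_z(p, dz)
  if (is.na(r)) 2 else -r
}

#' Refine a pRF fit from a grid seed
#'
#' Nelder-Mead simplex minimization of the negative correlation over
#' `(mu_x, mu_y, log sigma)`; the log parameterization keeps sigma
#' positive. The returned fit never scores below its seed: if the
#' optimizer fails to improve, the seed is returned (with
#' `converged = FALSE` when the iteration limit was hit).
#'
#' @param data A [timecourse()] or numeric vector.
#' @param stim,hrf Stimulus and HRF (ignored when `ctx` given).
#' @param seed Seed [prf_params()], typically from [grid_search()].
#' @param ctx Optional [fit_context()].
#' @param control `optim` control list; defaults
#'   `list(maxit = 600, reltol = 1e-8)` emulate fminsearch-style
#'   tolerances.
#' @return List of class `fit_result`: `prf`, `correlation`,
#'   `variance_explained`, `seed_used`, `converged`, `retained` (`NA`
#'   until [apply_filters()]).
#' @export
refine_fit <- function(data, stim = NULL, hrf = NULL, seed, ctx = NULL,
                       control = list(maxit = 600, reltol = 1e-8)) {
  ctx <- .as_ctx(ctx, stim, hrf)
  stopifnot(inherits(seed, "prf_params"))
  dz <- .zscore(.tc_values(data))
  if (is.null(dz)) {
    return(structure(list(prf = seed, correlation = NA_real_,
                          variance_explained = NA_real_, seed_used = seed,
                          converged = FALSE, retained = NA),
                     class = "fit_result"))
  }
  par0 <- c(seed$mu_x, seed$mu_y, log(seed$sigma))
  f0 <- .refine_obj(par0, ctx, dz)
  opt <- optim(par0, .refine_obj, ctx = ctx, dz = dz,
               method = "Nelder-Mead", control = control)
  if (is.finite(opt$value) && opt$value <= f0) {
    par <- opt$par; val <- opt$value
  } else {
    par <- par0; val <- f0
  }
  r <- if (val >= 2) NA_real_ else -val
  structure(list(prf = prf_params(par[1], par[2], exp(par[3])),
                 correlation = r, variance_explained = r^2,
                 seed_used = seed, converged = opt$convergence == 0,
                 retained = NA),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> center (%.3g, %.3g), sigma %.3g | r = %.4f (VE %.1f%%)%s\n",
    x$prf$mu_x, x$prf$mu_y, x$prf$sigma, x$correlation,
    100 * x$variance_explained,
    if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Fit pRFs for a matrix of time courses
#'
#' Runs the two-stage fit (grid search, then optional simplex refinement)
#' for every column of `data` against one stimulus and HRF, and applies the
#' retention rule. Deterministic: identical inputs give identical results.
#'
#' @param data Numeric matrix, time points x units.
#' @param stim A preprocessed [stimulus_movie()].
#' @param hrf An [hrf_params()] object.
#' @param grid A [grid_search_spec()].
#' @param refine Run [refine_fit()] after the grid search (default `TRUE`).
#' @param rule A [retention_rule()].
#' @param ctx Optional [fit_context()].
#' @param control Passed to [refine_fit()].
#' @return Data frame with one row per unit: `unit_id`, `mu_x`, `mu_y`,
#'   `sigma`, `polar_angle` (radians), `eccentricity`, `correlation`,
#'   `variance_explained`, `converged`, `retained`.
#' @export
fit_prfs <- function(data, stim = NULL, hrf = NULL,
                     grid = grid_search_spec(), refine = TRUE,
                     rule = retention_rule(), ctx = NULL,
                     control = list(maxit = 600, reltol = 1e-8)) {
  data <- as.matrix(data)
  ctx <- .as_ctx(ctx, stim, hrf)
  seeds <- grid_seeds(grid)
  Pz <- .standardize_cols(grid_predictions(grid, ctx = ctx))
  n <- ncol(data)
  out <- data.frame(unit_id = seq_len(n), mu_x = NA_real_, mu_y = NA_real_,
                    sigma = NA_real_, polar_angle = NA_real_,
                    eccentricity = NA_real_, correlation = NA_real_,
                    variance_explained = NA_real_, converged = NA,
                    retained = FALSE)
  for (u in seq_len(n)) {
    dz <- .zscore(data[, u])
    if (is.null(dz)) next  # zero-variance unit: flagged invalid, not fatal
    r <- .grid_cor(Pz, dz)
    i <- which.max(r)
    seed <- prf_params(seeds$mu_x[i], seeds$mu_y[i], seeds$sigma[i])
    if (refine) {
      fr <- refine_fit(dz, seed = seed, ctx = ctx, control = control)
      prf <- fr$prf; rr <- fr$correlation; conv <- fr$converged
    } else {
      prf <- seed; rr <- r[i]; conv <- TRUE
    }
    out$mu_x[u] <- prf$mu_x; out$mu_y[u] <- prf$mu_y
    out$sigma[u] <- prf$sigma
    out$polar_angle[u] <- polar_angle(prf)
    out$eccentricity[u] <- eccentricity(prf)
    out$correlation[u] <- rr
    out$variance_explained[u] <- rr^2
    out$converged[u] <- conv
  }
  apply_filters(out, rule)
}

#' Apply the retention rule to fitted pRFs
#'
#' @param results Data frame as returned by [fit_prfs()] (needs columns
#'   `eccentricity`, `sigma`, `variance_explained`).
#' @param rule A [retention_rule()].
#' @return `results` with its `retained` column set; fits with undefined
#'   (`NA`) goodness of fit are never retained.
#' @export
apply_filters <- function(results, rule = retention_rule()) {
  stopifnot(inherits(rule, "retention_rule"))
  ok <- !is.na(results$variance_explained) &
    results$eccentricity < rule$max_ecc &
    results$sigma > rule$min_sigma &
    results$variance_explained > rule$min_ve
  results$retained <- ok
  results
}
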