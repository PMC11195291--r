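# HRF estimation at fixed pRFs, and the alternating pRF/HRF fit.
#
# The six double-gamma parameters are fit per selected unit by Nelder-Mead
# on (delta, log alpha1, log alpha2, log beta1, log beta2, log ratio), with
# the pRF held fixed, maximizing the correlation objective; the group HRF
# is the element-wise median of the per-unit fits. To bound computation,
# only the top `select_frac` of units among those exceeding `min_ve`
# variance explained are fit (selection by VE, deterministic).

.hrf_to_par <- function(h) c(h$delta, log(h$alpha1), log(h$alpha2),
                             log(h$beta1), log(h$beta2), log(h$ratio))

.par_to_hrf <- function(p) hrf_params(max(p[1], 0), exp(p[2]), exp(p[3]),
                                      exp(p[4]), exp(p[5]), exp(p[6]))

#' Estimate a group HRF at fixed pRF parameters
#'
#' For each selected unit the six HRF parameters are optimized with the
#' unit's pRF (hence its stimulus-overlap trace) held fixed; the returned
#' HRF is the element-wise median across selected units. Units are
#' selected as the top `ceil(select_frac * m)` by variance explained among
#' the `m` units with VE > `min_ve` under the initial HRF.
#'
#' @param data Numeric matrix, time points x units.
#' @param prfs Data frame with `mu_x`, `mu_y`, `sigma` per unit (e.g. from
#'   [fit_prfs()] with `refine = FALSE`).
#' @param stim A preprocessed [stimulus_movie()].
#' @param init Initial [hrf_params()]; also the fallback when no unit
#'   passes the selection rule (with a warning).
#' @param select_frac Fraction of qualifying units to fit (default 0.15).
#' @param min_ve VE threshold defining the qualifying subset (default 0.20,
#'   strict).
#' @param span HRF kernel support, seconds.
#' @param control `optim` control for the 6-parameter simplex.
#' @return An [hrf_params()] object with attributes `n_selected` and
#'   `n_qualifying`.
#' @export
estimate_hrf <- function(data, prfs, stim, init = hrf_params(),
                         select_frac = 0.15, min_ve = 0.20, span = 40,
                         control = list(maxit = 3000, reltol = 1e-9)) {
  data <- as.matrix(data)
  stopifnot(nrow(prfs) == ncol(data))
  sp <- .stim_sparse(stim)
  kern0 <- hrf_kernel(init, sp$dt, span)
  O <- .overlap_matrix(sp, prfs$mu_x, prfs$mu_y, prfs$sigma, 8)
  n <- ncol(data)
  ve <- numeric(n)
  dzs <- vector("list", n)
  for (u in seq_len(n)) {
    dz <- .zscore(data[, u])
    dzs[[u]] <- dz
    pred <- cpp_convolve_causal(O[, u], kern0)
    r <- if (is.null(dz)) NA_real_ else cpp_cor_z(pred, dz)
    ve[u] <- r^2
  }
  qual <- which(!is.na(ve) & ve > min_ve)
  if (length(qual) == 0) {
    warning("no units exceed the VE threshold; returning the initial HRF")
    out <- init
    attr(out, "n_selected") <- 0L
    attr(out, "n_qualifying") <- 0L
    return(out)
  }
  n_sel <- ceiling(select_frac * length(qual))
  sel <- qual[order(ve[qual], decreasing = TRUE)[seq_len(n_sel)]]
  fitted <- matrix(NA_real_, length(sel), 6)
  for (j in seq_along(sel)) {
    u <- sel[j]
    ov <- O[, u]; dz <- dzs[[u]]
    obj <- function(p) {
      h <- tryCatch(.par_to_hrf(p), error = function(e) NULL)
      if (is.null(h)) return(2)
      pred <- cpp_convolve_causal(ov, hrf_kernel(h, sp$dt, span))
      r <- cpp_cor_z(pred, dz)
      if (is.na(r)) 2 else -r
    }
    p0 <- .hrf_to_par(init)
    opt <- optim(p0, obj, method = "Nelder-Mead", control = control)
    best <- if (opt$value <= obj(p0)) opt$par else p0
    h <- .par_to_hrf(best)
    fitted[j, ] <- c(h$delta, h$alpha1, h$alpha2, h$beta1, h$beta2, h$ratio)
  }
  med <- apply(fitted, 2, median)
  out <- hrf_params(med[1], med[2], med[3], med[4], med[5], med[6])
  attr(out, "n_selected") <- length(sel)
  attr(out, "n_qualifying") <- length(qual)
  out
}

#' Alternating pRF / HRF estimation
#'
#' Runs `n_iter` iterations of coordinate ascent: a coarse grid search
#' fixes the pRFs, the HRF is re-estimated at those pRFs, and the grid
#' search is repeated with the updated HRF. After the final iteration the
#' full two-stage fit (grid search plus simplex refinement) is run with the
#' converged HRF.
#'
#' @param data Numeric matrix, time points x units.
#' @param stim A preprocessed [stimulus_movie()].
#' @param init_hrf Initial [hrf_params()].
#' @param grid A [grid_search_spec()].
#' @param rule A [retention_rule()].
#' @param n_iter Alternation count (default 3).
#' @param fit_hrf With `FALSE` the HRF is held at `init_hrf` and the call
#'   reduces exactly to a single-pass [fit_prfs()].
#' @param select_frac,min_ve,span Passed to [estimate_hrf()].
#' @return List with `hrf` (converged [hrf_params()]), `fits` (final
#'   [fit_prfs()] table), and `history` (per-iteration median grid-search
#'   correlation).
#' @export
alternate_fit <- function(data, stim, init_hrf = hrf_params(),
                          grid = grid_search_spec(),
                          rule = retention_rule(), n_iter = 3,
                          fit_hrf = TRUE, select_frac = 0.15,
                          min_ve = 0.20, span = 40) {
  data <- as.matrix(data)
  hrf <- init_hrf
  history <- numeric(0)
  if (fit_hrf) {
    for (it in seq_len(n_iter)) {
      ctx <- fit_context(stim, hrf, span)
      seeds_fit <- fit_prfs(data, refine = FALSE, grid = grid, rule = rule,
                            ctx = ctx)
      history <- c(history, median(seeds_fit$correlation, na.rm = TRUE))
      hrf <- estimate_hrf(data, seeds_fit, stim, init = hrf,
                          select_frac = select_frac, min_ve = min_ve,
                          span = span)
    }
  }
  ctx <- fit_context(stim, hrf, span)
  fits <- fit_prfs(data, grid = grid, rule = rule, ctx = ctx)
  list(hrf = hrf, fits = fits, history = history)
}
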