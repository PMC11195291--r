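# Forward model: isometric 2-D Gaussian pRF and predicted BOLD time course.
#
# The predicted response is the spatial dot product of the stimulus movie
# with the pRF weight image, frame by frame, convolved with the HRF:
#   R(t) = sum_xy S(x, y, t) G(x, y) (*) h(t).
# G uses unit peak (G at the center is 1); under the correlation objective
# the normalization is irrelevant, and no amplitude or baseline terms are
# modelled for the same reason.

#' Gaussian pRF parameters
#'
#' @param mu_x,mu_y pRF center, degrees of visual angle.
#' @param sigma pRF size (standard deviation), degrees, > 0.
#' @return An object of class `prf_params`.
#' @export
prf_params <- function(mu_x, mu_y, sigma) {
  .check_num(mu_x, "mu_x"); .check_num(mu_y, "mu_y")
  .check_num(sigma, "sigma", positive = TRUE)
  structure(list(mu_x = mu_x, mu_y = mu_y, sigma = sigma),
            class = "prf_params")
}

#' @export
print.prf_params <- function(x, ...) {
  cat(sprintf(
    "<prf_params> center (%.3g, %.3g) deg, sigma %.3g deg (ecc %.3g, angle %.1f deg)\n",
    x$mu_x, x$mu_y, x$sigma, eccentricity(x), polar_angle(x) * 180 / pi))
  invisible(x)
}

#' Derived polar coordinates of a pRF center
#'
#' `eccentricity()` is `sqrt(mu_x^2 + mu_y^2)`; `polar_angle()` is
#' `atan2(mu_y, mu_x)` in radians, counter-clockwise from the positive x
#' axis.
#'
#' @param prf A [prf_params()] object (or anything with `mu_x`/`mu_y`).
#' @return Numeric scalar.
#' @export
eccentricity <- function(prf) sqrt(prf$mu_x^2 + prf$mu_y^2)

#' @rdname eccentricity
#' @export
polar_angle <- function(prf) atan2(prf$mu_y, prf$mu_x)

#' Gaussian pRF weight image
#'
#' Evaluates the unnormalized (unit-peak) isometric Gaussian
#' `exp(-((x-mu_x)^2 + (y-mu_y)^2) / (2 sigma^2))` at the pixel centers of
#' a grid.
#'
#' @param prf A [prf_params()] object.
#' @param grid A [field_grid()].
#' @return Numeric matrix `[height_px, width_px]`.
#' @export
gaussian_field <- function(prf, grid) {
  stopifnot(inherits(prf, "prf_params"))
  s2 <- 2 * prf$sigma^2
  ex <- exp(-(grid_xs(grid) - prf$mu_x)^2 / s2)
  ey <- exp(-(grid_ys(grid) - prf$mu_y)^2 / s2)
  outer(ey, ex)
}

#' Time course container
#'
#' @param values Signal values (arbitrary BOLD units).
#' @param dt Seconds per sample.
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(values, dt) {
  stopifnot(length(values) > 0, all(is.finite(values)))
  .check_num(dt, "dt", positive = TRUE)
  structure(list(values = as.numeric(values), dt = dt), class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d samples @ %g s, range [%.3g, %.3g]\n",
              length(x$values), x$dt, min(x$values), max(x$values)))
  invisible(x)
}

.tc_values <- function(x) if (inherits(x, "timecourse")) x$values else as.numeric(x)

# Compressed sparse representation of a movie for the C++ core:
# per-frame active-pixel index lists plus bounding boxes.
.stim_sparse <- function(movie) {
  d <- dim(movie$frames)
  h <- d[1]; w <- d[2]; nt <- d[3]
  nz <- which(movie$frames != 0)
  wt <- as.numeric(movie$frames[nz])
  frame <- (nz - 1L) %/% (h * w)           # 0-based frame index
  within <- (nz - 1L) %% (h * w)           # 0-based pixel index, col-major
  frame_ptr <- c(0L, cumsum(tabulate(frame + 1L, nbins = nt)))
  rows <- within %% h
  cols <- within %/% h
  row_lo <- row_hi <- col_lo <- col_hi <- integer(nt)
  for (t in seq_len(nt)) {
    a <- frame_ptr[t] + 1L; b <- frame_ptr[t + 1L]
    if (b >= a) {
      rr <- rows[a:b]; cc <- cols[a:b]
      row_lo[t] <- min(rr); row_hi[t] <- max(rr)
      col_lo[t] <- min(cc); col_hi[t] <- max(cc)
    }
  }
  sp <- list(frame_ptr = frame_ptr, idx = as.integer(within), wt = wt,
             xs = grid_xs(movie$grid), ys = grid_ys(movie$grid),
             row_lo = row_lo, row_hi = row_hi, col_lo = col_lo,
             col_hi = col_hi, nt = nt, dt = movie$frame_duration_s,
             binary = all(wt == 1))
  if (sp$binary) {
    # run-length encode each frame's columns: active pixels are ascending
    # in column-major order, so a new run starts wherever the predecessor
    # is not the pixel directly above in the same frame and column
    new_run <- c(TRUE, diff(nz) != 1L | rows[-1L] == 0L)
    run_start <- which(new_run)
    run_end <- c(run_start[-1L] - 1L, length(nz))
    rf <- frame[run_start]
    sp$run_ptr <- c(0L, cumsum(tabulate(rf + 1L, nbins = nt)))
    sp$run_col <- cols[run_start]
    sp$run_lo <- rows[run_start]
    sp$run_hi <- rows[run_end]
  }
  sp
}

# predictions for vectors of pRF parameters given a sparse stimulus and a
# sampled HRF kernel; returns nt x n matrix. Binary movies use the
# run-length-encoded fast path (same arithmetic per frame, grouped by
# column runs); fractional movies the per-pixel path.
.predict_matrix <- function(sp, mu_x, mu_y, sigma, kernel,
                            cutoff_sigmas = Inf) {
  if (isTRUE(sp$binary)) {
    cpp_predict_runs(sp$run_ptr, sp$run_col, sp$run_lo, sp$run_hi,
                     sp$xs, sp$ys,
                     as.numeric(mu_x), as.numeric(mu_y), as.numeric(sigma),
                     sp$row_lo, sp$row_hi, sp$col_lo, sp$col_hi,
                     kernel, cutoff_sigmas)
  } else {
    cpp_predict_many(sp$frame_ptr, sp$idx, sp$wt, sp$xs, sp$ys,
                     as.numeric(mu_x), as.numeric(mu_y), as.numeric(sigma),
                     sp$row_lo, sp$row_hi, sp$col_lo, sp$col_hi,
                     kernel, cutoff_sigmas)
  }
}

.overlap_matrix <- function(sp, mu_x, mu_y, sigma, cutoff_sigmas = Inf) {
  if (isTRUE(sp$binary)) {
    cpp_overlap_runs(sp$run_ptr, sp$run_col, sp$run_lo, sp$run_hi,
                     sp$xs, sp$ys,
                     as.numeric(mu_x), as.numeric(mu_y), as.numeric(sigma),
                     sp$row_lo, sp$row_hi, sp$col_lo, sp$col_hi,
                     cutoff_sigmas)
  } else {
    cpp_overlap_many(sp$frame_ptr, sp$idx, sp$wt, sp$xs, sp$ys,
                     as.numeric(mu_x), as.numeric(mu_y), as.numeric(sigma),
                     sp$row_lo, sp$row_hi, sp$col_lo, sp$col_hi,
                     cutoff_sigmas)
  }
}

#' Predicted BOLD time course for one pRF
#'
#' Per-frame overlap (spatial dot product of the stimulus frame with the
#' Gaussian weight image) convolved with the HRF. The output sampling
#' interval equals the movie's frame duration.
#'
#' @param stim A preprocessed [stimulus_movie()] (binary or fractional).
#' @param prf A [prf_params()] object.
#' @param hrf An [hrf_params()] object.
#' @param span HRF kernel support in seconds.
#' @return A [timecourse()].
#' @export
predict_timecourse <- function(stim, prf, hrf, span = 40) {
  stopifnot(inherits(stim, "stimulus_movie"), inherits(prf, "prf_params"),
            inherits(hrf, "hrf_params"))
  sp <- .stim_sparse(stim)
  k <- hrf_kernel(hrf, sp$dt, span)
  v <- .predict_matrix(sp, prf$mu_x, prf$mu_y, prf$sigma, k)[, 1]
  timecourse(v, sp$dt)
}
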