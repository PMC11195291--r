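# Parametric hemodynamic response function: the standard double-gamma
# (difference of two gamma densities), the form SPM uses.
#
#   h(t) = g(t - delta; alpha1, beta1) - g(t - delta; alpha2, beta2) / ratio
#
# with g(s; alpha, beta) the gamma density beta^alpha s^(alpha-1)
# exp(-beta s) / Gamma(alpha) and h = 0 for t <= delta. The canonical SPM
# parameters (delta 0, shapes 6 and 16, rates 1 and 1, ratio 6) place the
# positive peak at (alpha1 - 1) / beta1 = 5 s.

#' Double-gamma HRF parameters (shape/rate form)
#'
#' @param delta Onset delay, seconds (>= 0).
#' @param alpha1,alpha2 Shapes of the response and undershoot gamma
#'   densities (> 0).
#' @param beta1,beta2 Rates (1/seconds) of the response and undershoot
#'   gamma densities (> 0).
#' @param ratio Response-to-undershoot amplitude ratio (> 0); the
#'   undershoot density is scaled by `1/ratio`.
#' @return An object of class `hrf_params`.
#' @seealso [hrf_params_peaktime()] for the peak-time/dispersion
#'   parameterization.
#' @export
hrf_params <- function(delta = 0, alpha1 = 6, alpha2 = 16,
                       beta1 = 1, beta2 = 1, ratio = 6) {
  .check_num(delta, "delta", nonneg = TRUE)
  for (nm in c("alpha1", "alpha2", "beta1", "beta2", "ratio"))
    .check_num(get(nm), nm, positive = TRUE)
  structure(list(delta = delta, alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2, ratio = ratio),
            class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf(
    "<hrf_params> delta %.3g s | response a=%.3g b=%.3g | undershoot a=%.3g b=%.3g | ratio %.3g\n",
    x$delta, x$alpha1, x$beta1, x$alpha2, x$beta2, x$ratio))
  invisible(x)
}

#' HRF parameters from peak times and dispersions
#'
#' SPM-style parameterization: `alpha = peak / dispersion`,
#' `beta = 1 / dispersion`. The gamma-density mode is then
#' `peak - dispersion` (5 s and 15 s for the canonical 6/16 with unit
#' dispersions).
#'
#' @param delta Onset delay, seconds.
#' @param peak1,peak2 Time-to-peak parameters of response and undershoot,
#'   seconds.
#' @param disp1,disp2 Dispersions, seconds.
#' @param ratio Response-to-undershoot ratio.
#' @return An [hrf_params()] object.
#' @export
hrf_params_peaktime <- function(delta = 0, peak1 = 6, peak2 = 16,
                                disp1 = 1, disp2 = 1, ratio = 6) {
  hrf_params(delta, peak1 / disp1, peak2 / disp2, 1 / disp1, 1 / disp2, ratio)
}

#' Peak-time view of HRF parameters
#'
#' Inverse of [hrf_params_peaktime()].
#'
#' @param params An [hrf_params()] object.
#' @return Named list with `delta`, `peak1`, `peak2`, `disp1`, `disp2`,
#'   `ratio`.
#' @export
hrf_peaktime <- function(params) {
  stopifnot(inherits(params, "hrf_params"))
  list(delta = params$delta,
       peak1 = params$alpha1 / params$beta1,
       peak2 = params$alpha2 / params$beta2,
       disp1 = 1 / params$beta1, disp2 = 1 / params$beta2,
       ratio = params$ratio)
}

#' Evaluate the double-gamma HRF
#'
#' @param params An [hrf_params()] object.
#' @param t Sample times in seconds (any order; typically an ascending
#'   grid).
#' @return Response values; zero for `t <= delta`.
#' @export
hrf_curve <- function(params, t) {
  stopifnot(inherits(params, "hrf_params"))
  ts <- t - params$delta
  h <- numeric(length(t))
  pos <- ts > 0
  h[pos] <- dgamma(ts[pos], shape = params$alpha1, rate = params$beta1) -
    dgamma(ts[pos], shape = params$alpha2, rate = params$beta2) / params$ratio
  h
}

#' Sampled HRF kernel for discrete convolution
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling interval, seconds.
#' @param span Kernel support, seconds (default 40, enough for the
#'   canonical undershoot to decay).
#' @return Numeric vector `hrf_curve(params, seq(0, span, by = dt))`.
#' @export
hrf_kernel <- function(params, dt, span = 40) {
  .check_num(dt, "dt", positive = TRUE)
  hrf_curve(params, seq(0, span, by = dt))
}

#' Convolve a signal with the HRF
#'
#' Causal discrete convolution truncated to the input length:
#' `y[n] = sum_j x[n-j] h[j dt]`. A unit impulse at the first sample
#' returns the sampled HRF.
#'
#' @param signal Uniformly sampled input time series.
#' @param params An [hrf_params()] object.
#' @param dt Sampling interval of `signal`, seconds.
#' @param span Kernel support in seconds (see [hrf_kernel()]).
#' @return Convolved time series, same length as `signal`.
#' @export
convolve_hrf <- function(signal, params, dt, span = 40) {
  k <- hrf_kernel(params, dt, span)
  cpp_convolve_causal(as.numeric(signal), k)
}
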