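# Log-eccentricity warp: r' = c * log(1 + k * r).
#
# The natural logarithm is used throughout, consistent with Schwartz-type
# log-polar models of the visual-to-cortical mapping; any other base is
# absorbed into the scale constant c, so results are base-invariant.

# below this k the warp is treated as the identity (the k -> 0 limit),
# avoiding catastrophic cancellation in c = rmax / log(1 + k * rmax)
.K_IDENTITY_EPS <- 1e-6

#' Scale constant of the log-eccentricity warp
#'
#' Computes `c = rmax / log(1 + k * rmax)` (natural log), the scale constant
#' that pins the warp at the aperture edge: `log_map(rmax) == rmax`.
#'
#' @param k Dimensionless distortion factor, > 0. Larger `k` pulls more of
#'   the stimulus toward the fovea; `k = 5` approximates the cortical
#'   magnification of human early visual cortex.
#' @param rmax Maximum stimulus eccentricity in degrees of visual angle, > 0.
#' @return The scale constant in degrees.
#' @examples
#' scale_constant(5, 8)  # 8 / log(41) ~= 2.154
#' @export
scale_constant <- function(k, rmax) {
  .check_num(k, "k", positive = TRUE)
  .check_num(rmax, "rmax", positive = TRUE)
  rmax / log1p(k * rmax)
}

#' Warp specification
#'
#' Bundles the parameters of the log-eccentricity mapping. When `c` is not
#' supplied it is derived with [scale_constant()]; for `k` below `1e-6` the
#' warp degenerates to the identity (the zero-distortion limit) and `c`
#' follows the limiting convention `c -> 1/k` so that `c * log(1 + k*r) -> r`.
#'
#' @param k Distortion factor, >= 0.
#' @param rmax Maximum eccentricity in degrees, > 0.
#' @param c Optional scale constant; derived from `k` and `rmax` by default.
#' @return An object of class `warp_spec`.
#' @export
warp_spec <- function(k = 5, rmax = 8, c = NULL) {
  .check_num(k, "k", nonneg = TRUE)
  .check_num(rmax, "rmax", positive = TRUE)
  if (is.null(c)) {
    c <- if (k < .K_IDENTITY_EPS) NA_real_ else scale_constant(k, rmax)
  } else {
    .check_num(c, "c", positive = TRUE)
  }
  structure(list(k = k, rmax = rmax, c = c), class = "warp_spec")
}

#' @export
print.warp_spec <- function(x, ...) {
  cat(sprintf("<warp_spec> k = %g, rmax = %g deg, c = %g deg%s\n",
              x$k, x$rmax, x$c,
              if (x$k < .K_IDENTITY_EPS) " (identity limit)" else ""))
  invisible(x)
}

#' Forward log-eccentricity map
#'
#' Maps fixed-space eccentricity `r` to `r' = c * log(1 + k * r)`. Strictly
#' monotone increasing, with `log_map(0) = 0` and `log_map(rmax) = rmax`
#' when `c` is derived by [scale_constant()]. For `k` in the identity limit
#' the input is returned unchanged.
#'
#' @param r Eccentricities in degrees, >= 0 (vectorized).
#' @param spec A [warp_spec()].
#' @return Mapped eccentricities in degrees.
#' @export
log_map <- function(r, spec) {
  stopifnot(inherits(spec, "warp_spec"))
  if (any(!is.finite(r)) || any(r < 0))
    stop("`r` must be finite and >= 0", call. = FALSE)
  if (spec$k < .K_IDENTITY_EPS) return(r)
  spec$c * log1p(spec$k * r)
}

#' Inverse log-eccentricity map
#'
#' Inverts [log_map()]: returns `(exp(r'/c) - 1) / k`. This is the radius in
#' the warped (log-bar) image at which a fixed-space feature of eccentricity
#' `r'` appears.
#'
#' @param r_prime Warped eccentricities in degrees, >= 0 (vectorized).
#' @param spec A [warp_spec()].
#' @return Fixed-space eccentricities in degrees.
#' @export
inverse_log_map <- function(r_prime, spec) {
  stopifnot(inherits(spec, "warp_spec"))
  if (any(!is.finite(r_prime)) || any(r_prime < 0))
    stop("`r_prime` must be finite and >= 0", call. = FALSE)
  if (spec$k < .K_IDENTITY_EPS) return(r_prime)
  expm1(r_prime / spec$c) / spec$k
}
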