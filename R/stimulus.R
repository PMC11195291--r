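# Stimulus generation: fixed-bar aperture movies, log-bar warping, and
# preprocessing to the resolution used for model fitting.
#
# Coordinate convention: degrees of visual angle, x rightward, y upward,
# origin at fixation. Pixel centers sit at half-integer offsets from the
# image center; row 1 is the top of the image (largest y). Movies are
# stored as [height_px, width_px, n_frames] arrays with values in {0, 1}
# (or fractional coverage in [0, 1] after non-binarized preprocessing).

#' Pixel grid of the visual field
#'
#' @param width_px,height_px Pixel counts (height defaults to width).
#' @param deg_per_px Degrees of visual angle per pixel. Exactly one of
#'   `deg_per_px` and `rmax` must be given; with `rmax` the grid spans the
#'   circular aperture exactly (`deg_per_px = 2 * rmax / width_px`).
#' @param rmax Optional aperture radius used to derive `deg_per_px`.
#' @return An object of class `field_grid`.
#' @export
field_grid <- function(width_px, height_px = width_px,
                       deg_per_px = NULL, rmax = NULL) {
  stopifnot(width_px >= 1, height_px >= 1)
  if (is.null(deg_per_px)) {
    if (is.null(rmax)) stop("give either `deg_per_px` or `rmax`", call. = FALSE)
    deg_per_px <- 2 * rmax / width_px
  }
  .check_num(deg_per_px, "deg_per_px", positive = TRUE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 deg_per_px = deg_per_px),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d px, %.5f deg/px (%.2f x %.2f deg)\n",
              x$width_px, x$height_px, x$deg_per_px,
              x$width_px * x$deg_per_px, x$height_px * x$deg_per_px))
  invisible(x)
}

#' Pixel-center coordinates in degrees
#'
#' `grid_xs()` returns the x coordinate of each column (ascending);
#' `grid_ys()` the y coordinate of each row (descending: row 1 is the top).
#'
#' @param grid A [field_grid()].
#' @return Numeric vector of coordinates in degrees.
#' @export
grid_xs <- function(grid) {
  (seq_len(grid$width_px) - (grid$width_px + 1) / 2) * grid$deg_per_px
}

#' @rdname grid_xs
#' @export
grid_ys <- function(grid) {
  ((grid$height_px + 1) / 2 - seq_len(grid$height_px)) * grid$deg_per_px
}

#' One bar sweep
#'
#' A bar of fixed width drifting at constant speed along `direction`. At the
#' default settings one 45 s sweep at 0.4 deg/s covers 18 deg: the 16 deg
#' aperture diameter plus one 2 deg bar width, a full traverse.
#'
#' @param direction Motion direction in degrees (counter-clockwise from the
#'   positive x axis). The bar is perpendicular to the motion axis.
#' @param bar_width Bar width in degrees (fixed space).
#' @param speed Drift speed in degrees per second (fixed space).
#' @param duration Sweep duration in seconds.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(direction, bar_width = 2, speed = 0.4, duration = 45) {
  .check_num(direction, "direction")
  .check_num(bar_width, "bar_width", positive = TRUE)
  .check_num(speed, "speed", positive = TRUE)
  .check_num(duration, "duration", positive = TRUE)
  structure(list(direction = direction, bar_width = bar_width,
                 speed = speed, duration = duration), class = "sweep_spec")
}

#' Run structure
#'
#' A run is a 2 s blank, eight 45 s sweeps in pseudorandom directions, and a
#' 4 s blank: 366 s in total. The default direction set is 8 directions at
#' 45 deg increments (4 orientations x 2 motion senses), one of each per
#' run, shuffled by `rng_seed`.
#'
#' @param sweeps Optional list of [sweep_spec()]s; built from `directions`
#'   when `NULL`.
#' @param pre_blank_s,post_blank_s Blank durations in seconds.
#' @param frame_rate_hz Frames per second of the assembled movie.
#' @param rng_seed Integer seed for the sweep-direction shuffle.
#' @param directions Candidate directions in degrees.
#' @param bar_width,speed,sweep_duration_s Sweep geometry defaults.
#' @return An object of class `run_spec`.
#' @export
run_spec <- function(sweeps = NULL, pre_blank_s = 2, post_blank_s = 4,
                     frame_rate_hz = 1, rng_seed = 1L,
                     directions = seq(0, 315, by = 45),
                     bar_width = 2, speed = 0.4, sweep_duration_s = 45) {
  .check_num(pre_blank_s, "pre_blank_s", nonneg = TRUE)
  .check_num(post_blank_s, "post_blank_s", nonneg = TRUE)
  .check_num(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  if (is.null(sweeps)) {
    ord <- with_seed(rng_seed, sample.int(length(directions)))
    sweeps <- lapply(directions[ord], sweep_spec,
                     bar_width = bar_width, speed = speed,
                     duration = sweep_duration_s)
  }
  stopifnot(length(sweeps) >= 1,
            all(vapply(sweeps, inherits, TRUE, "sweep_spec")))
  total <- pre_blank_s + sum(vapply(sweeps, `[[`, 0, "duration")) + post_blank_s
  structure(list(pre_blank_s = pre_blank_s, sweeps = sweeps,
                 post_blank_s = post_blank_s, frame_rate_hz = frame_rate_hz,
                 rng_seed = as.integer(rng_seed), total_duration_s = total),
            class = "run_spec")
}

#' Stimulus movie container
#'
#' @param frames `[height_px, width_px, n_frames]` array; binary apertures
#'   hold values in `{0, 1}`, preprocessed movies may hold fractional
#'   coverage in `[0, 1]`.
#' @param grid The [field_grid()] calibrating pixels to degrees.
#' @param frame_duration_s Seconds per frame.
#' @param label `"fixed"` or `"log"`.
#' @param rmax Aperture radius in degrees.
#' @return An object of class `stimulus_movie`.
#' @export
stimulus_movie <- function(frames, grid, frame_duration_s,
                           label = c("fixed", "log"), rmax) {
  label <- match.arg(label)
  stopifnot(length(dim(frames)) == 3L,
            dim(frames)[1] == grid$height_px,
            dim(frames)[2] == grid$width_px)
  .check_num(frame_duration_s, "frame_duration_s", positive = TRUE)
  .check_num(rmax, "rmax", positive = TRUE)
  structure(list(frames = frames, grid = grid,
                 frame_duration_s = frame_duration_s,
                 label = label, rmax = rmax),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<stimulus_movie:%s> %d x %d px, %d frames @ %g s (%g s total), rmax %g deg\n",
    x$label, d[1], d[2], d[3], x$frame_duration_s,
    d[3] * x$frame_duration_s, x$rmax))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A [stimulus_movie()].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

# strip-and-disc mask used by make_bar_frame / make_sweep.
# Returns precomputed projection and squared-radius matrices for a grid.
.bar_geometry <- function(grid, direction) {
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  th <- direction * pi / 180
  proj <- outer(ys * sin(th), xs * cos(th), `+`)  # x cos + y sin
  r2 <- outer(ys^2, xs^2, `+`)
  list(proj = proj, r2 = r2)
}

#' Render one bar frame
#'
#' Pixels whose perpendicular distance to the bar axis is at most half the
#' bar width, and which lie inside the `rmax` disc, are set to 1.
#'
#' @param bar_center_offset Bar-center position along the motion axis,
#'   degrees.
#' @param sweep A [sweep_spec()].
#' @param grid A [field_grid()].
#' @param rmax Aperture radius in degrees.
#' @return Integer matrix `[height_px, width_px]` of 0/1.
#' @export
make_bar_frame <- function(bar_center_offset, sweep, grid, rmax) {
  stopifnot(inherits(sweep, "sweep_spec"))
  if (sweep$bar_width < grid$deg_per_px)
    warning("bar width is thinner than one pixel at this grid resolution")
  geom <- .bar_geometry(grid, sweep$direction)
  m <- (abs(geom$proj - bar_center_offset) <= sweep$bar_width / 2) &
    (geom$r2 <= rmax^2)
  matrix(as.integer(m), grid$height_px, grid$width_px)
}

#' Render all frames of one sweep
#'
#' The bar-center offset advances linearly at the sweep speed from
#' `-span/2` to `+span/2` where `span = speed * duration`; frames are
#' sampled at frame centers `(i - 1/2) / frame_rate_hz`. A full traverse
#' requires `span >= 2 * rmax + bar_width` (18 deg at the defaults).
#'
#' @param sweep A [sweep_spec()].
#' @param grid A [field_grid()].
#' @param rmax Aperture radius in degrees.
#' @param frame_rate_hz Frames per second.
#' @return Integer array `[height_px, width_px, n_frames]`.
#' @export
make_sweep <- function(sweep, grid, rmax, frame_rate_hz = 1) {
  stopifnot(inherits(sweep, "sweep_spec"))
  span <- sweep$speed * sweep$duration
  if (span < 2 * rmax + sweep$bar_width - 1e-9)
    warning(sprintf(
      "sweep spans %.3g deg < aperture + bar width (%.3g deg): not a full traverse",
      span, 2 * rmax + sweep$bar_width))
  nf <- as.integer(round(sweep$duration * frame_rate_hz))
  if (sweep$bar_width < grid$deg_per_px)
    warning("bar width is thinner than one pixel at this grid resolution")
  geom <- .bar_geometry(grid, sweep$direction)
  disc <- geom$r2 <= rmax^2
  out <- array(0L, c(grid$height_px, grid$width_px, nf))
  t_mid <- (seq_len(nf) - 0.5) / frame_rate_hz
  offs <- -span / 2 + sweep$speed * t_mid
  half <- sweep$bar_width / 2
  for (i in seq_len(nf)) {
    m <- (abs(geom$proj - offs[i]) <= half) & disc
    out[, , i] <- as.integer(m)
  }
  out
}

#' Assemble a full fixed-bar run
#'
#' Concatenates the pre-blank, the seeded sweep sequence, and the post-blank
#' into one binary movie. At the defaults the run lasts
#' 2 + 8 x 45 + 4 = 366 s; the frame count is `round(366 * frame_rate_hz)`.
#' The same `run` (including its seed) always yields a bit-identical movie.
#'
#' @param run A [run_spec()].
#' @param grid A [field_grid()].
#' @param rmax Aperture radius in degrees.
#' @return A [stimulus_movie()] with label `"fixed"`.
#' @export
assemble_run <- function(run, grid, rmax) {
  stopifnot(inherits(run, "run_spec"))
  fps <- run$frame_rate_hz
  n_pre <- as.integer(round(run$pre_blank_s * fps))
  n_post <- as.integer(round(run$post_blank_s * fps))
  chunks <- lapply(run$sweeps, make_sweep, grid = grid, rmax = rmax,
                   frame_rate_hz = fps)
  n_sw <- vapply(chunks, function(a) dim(a)[3], 0L)
  nt <- n_pre + sum(n_sw) + n_post
  frames <- array(0L, c(grid$height_px, grid$width_px, nt))
  at <- n_pre
  for (ch in chunks) {
    frames[, , at + seq_len(dim(ch)[3])] <- ch
    at <- at + dim(ch)[3]
  }
  stimulus_movie(frames, grid, 1 / fps, "fixed", rmax)
}

# Precompute the backward-sampling map realizing the log warp on a grid.
# Output pixel at polar (theta, r_out) displays the fixed-bar content at
# (theta, log_map(r_out)): a fixed-space feature at eccentricity rho thus
# appears at inverse_log_map(rho), giving the thin/slow foveal bar and the
# wide/fast peripheral bar, i.e. constant speed on a log-mapped cortex.
# Returns bilinear indices (4 columns) and weights; pixels outside the rmax
# disc get zero weight.
.warp_map <- function(grid, spec) {
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  h <- grid$height_px; w <- grid$width_px
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)
  r_out <- sqrt(X^2 + Y^2)
  inside <- r_out <= spec$rmax
  r_src <- log_map(pmin(r_out, spec$rmax), spec)
  scl <- ifelse(r_out > 0, r_src / r_out, 1)
  xsrc <- X * scl
  ysrc <- Y * scl
  # fractional pixel coordinates (1-based, pixel centers at integers)
  colf <- xsrc / grid$deg_per_px + (w + 1) / 2
  rowf <- (h + 1) / 2 - ysrc / grid$deg_per_px
  colf <- as.vector(colf); rowf <- as.vector(rowf)
  c0 <- floor(colf); r0 <- floor(rowf)
  fc <- colf - c0; fr <- rowf - r0
  wts <- cbind((1 - fr) * (1 - fc), (1 - fr) * fc, fr * (1 - fc), fr * fc)
  wts <- wts * as.vector(inside)
  idx <- matrix(1L, length(r_out), 4)
  for (j in 1:4) {
    rr <- as.vector(r0) + (j - 1) %/% 2
    cc <- as.vector(c0) + (j - 1) %% 2
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    wts[!ok, j] <- 0
    idx[ok, j] <- (cc[ok] - 1L) * h + rr[ok]
  }
  list(idx = idx, wts = wts)
}

#' Warp a fixed-bar movie into a log-bar movie
#'
#' Applies the log-eccentricity warp frame by frame: the output pixel at
#' polar coordinates `(theta, r)` backward-samples the source frame at
#' `(theta, log_map(r))` with bilinear interpolation, so a fixed-space
#' feature at eccentricity `rho` appears at `inverse_log_map(rho)`. Polar
#' angle is unchanged; pixels beyond `rmax` are zero. For `k` in the
#' identity limit the frames are returned unchanged (relabelled `"log"`).
#'
#' @param movie A fixed-space [stimulus_movie()].
#' @param spec A [warp_spec()]; its `rmax` must match the movie's.
#' @param rebinarize Threshold the interpolated frames at 0.5 back to
#'   `{0, 1}` (default `TRUE`).
#' @return A [stimulus_movie()] with label `"log"`.
#' @export
warp_movie <- function(movie, spec, rebinarize = TRUE) {
  stopifnot(inherits(movie, "stimulus_movie"), inherits(spec, "warp_spec"))
  if (movie$label != "fixed")
    stop("`movie` must be in fixed (unwarped) space", call. = FALSE)
  if (abs(spec$rmax - movie$rmax) > 1e-9)
    stop("warp rmax does not match movie rmax", call. = FALSE)
  out <- movie
  out$label <- "log"
  if (spec$k < .K_IDENTITY_EPS) return(out)
  map <- .warp_map(movie$grid, spec)
  d <- dim(movie$frames)
  nt <- d[3]
  frames <- if (rebinarize) array(0L, d) else array(0, d)
  for (t in seq_len(nt)) {
    f <- movie$frames[, , t]
    v <- map$wts[, 1] * f[map$idx[, 1]] + map$wts[, 2] * f[map$idx[, 2]] +
      map$wts[, 3] * f[map$idx[, 3]] + map$wts[, 4] * f[map$idx[, 4]]
    frames[, , t] <- if (rebinarize) as.integer(v >= 0.5) else v
  }
  out$frames <- frames
  out
}

# block mean of a square-factor downsample (f divides both dims)
.block_mean <- function(m, f) {
  h <- nrow(m); w <- ncol(m)
  m2 <- matrix(colMeans(matrix(m, nrow = f)), nrow = h / f)       # rows
  t(matrix(colMeans(matrix(t(m2), nrow = f)), nrow = w / f))      # cols
}

# separable linear interpolation resample of a matrix to (th, tw)
.linear_resample2d <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  src_r <- (seq_len(th) - 0.5) * h / th + 0.5
  src_c <- (seq_len(tw) - 0.5) * w / tw + 0.5
  interp1 <- function(mat, src) {
    n <- nrow(mat)
    lo <- pmin(pmax(floor(src), 1), n)
    hi <- pmin(lo + 1, n)
    fr <- pmin(pmax(src - lo, 0), 1)
    mat[lo, , drop = FALSE] * (1 - fr) + mat[hi, , drop = FALSE] * fr
  }
  t(interp1(t(interp1(m, src_r)), src_c))
}

#' Downsample a stimulus movie for model fitting
#'
#' Spatial linear downsampling (block averaging when the target divides the
#' source, separable linear interpolation otherwise) followed by linear
#' temporal resampling, then optional rebinarization at 0.5. The defaults
#' reduce a 540 x 540 render to the 108 x 108 x 366 movie used for fitting.
#'
#' @param movie A [stimulus_movie()].
#' @param target_px Target spatial resolution (square), <= source.
#' @param target_frames Target frame count, <= source.
#' @param binarize Threshold the resampled movie at 0.5 (default `TRUE`);
#'   with `FALSE` fractional coverage in `[0, 1]` is kept.
#' @return A [stimulus_movie()] at the target resolution.
#' @export
preprocess_movie <- function(movie, target_px = 108, target_frames = 366,
                             binarize = TRUE) {
  stopifnot(inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  if (target_px > min(d[1], d[2]) || target_frames > d[3])
    stop("upsampling is not supported", call. = FALSE)
  h <- d[1]; w <- d[2]; nt <- d[3]
  divisible <- h == w && h %% target_px == 0
  f <- if (divisible) h %/% target_px else NA_integer_
  sp <- matrix(0, target_px * target_px, nt)
  for (t in seq_len(nt)) {
    fr <- movie$frames[, , t]
    storage.mode(fr) <- "double"
    sm <- if (divisible) .block_mean(fr, f)
          else .linear_resample2d(fr, target_px, target_px)
    sp[, t] <- sm
  }
  # temporal linear resample at target frame centers
  total_s <- nt * movie$frame_duration_s
  t_src <- (seq_len(nt) - 0.5) * movie$frame_duration_s
  t_tgt <- (seq_len(target_frames) - 0.5) * total_s / target_frames
  lo <- findInterval(t_tgt, t_src)
  lo <- pmin(pmax(lo, 1L), nt)
  hi <- pmin(lo + 1L, nt)
  fr_w <- ifelse(hi > lo, (t_tgt - t_src[lo]) / (t_src[hi] - t_src[lo]), 0)
  fr_w <- pmin(pmax(fr_w, 0), 1)
  res <- sp[, lo, drop = FALSE] * rep(1 - fr_w, each = nrow(sp)) +
    sp[, hi, drop = FALSE] * rep(fr_w, each = nrow(sp))
  frames <- array(res, c(target_px, target_px, target_frames))
  if (binarize) {
    frames <- array(as.integer(frames >= 0.5),
                    c(target_px, target_px, target_frames))
  }
  new_grid <- field_grid(target_px, target_px,
                         deg_per_px = movie$grid$deg_per_px * w / target_px)
  stimulus_movie(frames, new_grid, total_s / target_frames, movie$label,
                 movie$rmax)
}

#' Build a preprocessed stimulus movie end to end
#'
#' Renders a fixed-bar run at native resolution, optionally warps it into a
#' log-bar movie, and preprocesses it to the fitting resolution. Rendering
#' and warping are done sweep-by-sweep to bound memory.
#'
#' @param mode `"fixed"` or `"log"`.
#' @param warp A [warp_spec()] (used when `mode = "log"`; its `rmax` sets
#'   the aperture radius).
#' @param run A [run_spec()]; its frame rate is the render frame rate.
#' @param render_px Native render resolution (paper source: 540).
#' @param target_px,target_frames Preprocessing targets.
#' @param binarize Passed to [preprocess_movie()].
#' @return A preprocessed [stimulus_movie()].
#' @export
build_stimulus <- function(mode = c("fixed", "log"), warp = warp_spec(),
                           run = run_spec(), render_px = 540,
                           target_px = 108, target_frames = 366,
                           binarize = TRUE) {
  mode <- match.arg(mode)
  rmax <- warp$rmax
  grid <- field_grid(render_px, rmax = rmax)
  fps <- run$frame_rate_hz
  map <- if (mode == "log" && warp$k >= .K_IDENTITY_EPS)
    .warp_map(grid, warp) else NULL
  divisible <- render_px %% target_px == 0
  f <- if (divisible) render_px %/% target_px else NA_integer_

  shrink <- function(chunk) {
    nt <- dim(chunk)[3]
    out <- matrix(0, target_px * target_px, nt)
    for (t in seq_len(nt)) {
      fr <- chunk[, , t]
      if (!is.null(map)) {
        v <- map$wts[, 1] * fr[map$idx[, 1]] + map$wts[, 2] * fr[map$idx[, 2]] +
          map$wts[, 3] * fr[map$idx[, 3]] + map$wts[, 4] * fr[map$idx[, 4]]
        fr <- matrix(as.numeric(v >= 0.5), render_px, render_px)
      } else {
        storage.mode(fr) <- "double"
      }
      out[, t] <- if (divisible) .block_mean(fr, f)
                  else .linear_resample2d(fr, target_px, target_px)
    }
    out
  }

  n_pre <- as.integer(round(run$pre_blank_s * fps))
  n_post <- as.integer(round(run$post_blank_s * fps))
  pieces <- vector("list", length(run$sweeps) + 2)
  pieces[[1]] <- matrix(0, target_px * target_px, n_pre)
  for (i in seq_along(run$sweeps)) {
    sw <- make_sweep(run$sweeps[[i]], grid, rmax, fps)
    pieces[[i + 1]] <- shrink(sw)
  }
  pieces[[length(pieces)]] <- matrix(0, target_px * target_px, n_post)
  sp <- do.call(cbind, pieces)
  nt <- ncol(sp)

  total_s <- nt / fps
  t_src <- (seq_len(nt) - 0.5) / fps
  t_tgt <- (seq_len(target_frames) - 0.5) * total_s / target_frames
  lo <- pmin(pmax(findInterval(t_tgt, t_src), 1L), nt)
  hi <- pmin(lo + 1L, nt)
  fr_w <- ifelse(hi > lo, (t_tgt - t_src[lo]) / (t_src[hi] - t_src[lo]), 0)
  fr_w <- pmin(pmax(fr_w, 0), 1)
  res <- sp[, lo, drop = FALSE] * rep(1 - fr_w, each = nrow(sp)) +
    sp[, hi, drop = FALSE] * rep(fr_w, each = nrow(sp))
  frames <- array(res, c(target_px, target_px, target_frames))
  if (binarize)
    frames <- array(as.integer(frames >= 0.5), dim(frames))
  new_grid <- field_grid(target_px,
                         deg_per_px = grid$deg_per_px * render_px / target_px)
  stimulus_movie(frames, new_grid, total_s / target_frames,
                 if (mode == "log") "log" else "fixed", rmax)
}
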