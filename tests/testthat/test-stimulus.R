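test_that("bar frames are strip-and-disc masks with the analytic area", {
  grid <- field_grid(256, rmax = 8)
  sw <- sweep_spec(direction = 0, bar_width = 2, speed = 0.4, duration = 45)
  f <- make_bar_frame(0, sw, grid, 8)
  expect_true(all(f %in% c(0L, 1L)))
  # centered vertical strip of half-width 1 deg clipped to the 8 deg disc:
  # area = 2 (a sqrt(R^2 - a^2) + R^2 asin(a/R)), frozen from closed form
  area_px <- sum(f) * grid$deg_per_px^2
  expect_equal(area_px, 31.916470255899914, tolerance = 0.02 * 31.9)
  # bar fully outside the aperture -> empty frame
  expect_equal(sum(make_bar_frame(8 + 1, sw, grid, 8)), 0)
  # symmetric offsets give mirror-identical areas
  expect_equal(sum(make_bar_frame(3, sw, grid, 8)),
               sum(make_bar_frame(-3, sw, grid, 8)))
})

test_that("sweeps advance linearly and cover the full traverse", {
  grid <- field_grid(64, rmax = 8)
  sw <- sweep_spec(direction = 0, bar_width = 2, speed = 0.4, duration = 45)
  expect_equal(sw$speed * sw$duration, 2 * 8 + 2)  # aperture + bar width
  st <- make_sweep(sw, grid, 8, frame_rate_hz = 2)
  expect_equal(dim(st)[3], 90)
  # first and last frames: bar only touching the aperture edge
  xs <- grid_xs(grid)
  first_cols <- which(colSums(st[, , 1]) > 0)
  expect_true(all(abs(xs[first_cols]) >= 8 - sw$bar_width))
  last_cols <- which(colSums(st[, , 90]) > 0)
  expect_true(all(abs(xs[last_cols]) >= 8 - sw$bar_width))
  # bar center advances at `speed`: compare active-column centroid drift
  mid <- function(t) mean(xs[which(colSums(st[, , t]) > 0)])
  expect_equal(mid(60) - mid(30), 0.4 * 15, tolerance = 0.3)
  # short sweep warns about incomplete traverse
  expect_warning(make_sweep(sweep_spec(0, duration = 10), grid, 8, 1),
                 "traverse")
})

test_that("assembled runs have the stated duration, blanks, and determinism", {
  grid <- field_grid(32, rmax = 8)
  for (fps in c(1, 2)) {
    m <- assemble_run(run_spec(frame_rate_hz = fps, rng_seed = 42), grid, 8)
    expect_equal(n_frames(m), round(366 * fps))
    expect_equal(n_frames(m) * m$frame_duration_s, 366)
    # pre- and post-blank frames are empty
    expect_equal(sum(m$frames[, , seq_len(round(2 * fps))]), 0)
    expect_equal(sum(m$frames[, , n_frames(m) - seq_len(round(4 * fps)) + 1]), 0)
  }
  a <- assemble_run(run_spec(rng_seed = 42), grid, 8)
  b <- assemble_run(run_spec(rng_seed = 42), grid, 8)
  expect_identical(a$frames, b$frames)
  c2 <- assemble_run(run_spec(rng_seed = 43), grid, 8)
  expect_false(identical(a$frames, c2$frames))
})

test_that("warp preserves polar angle and the aperture edge", {
  grid <- field_grid(128, rmax = 8)
  ws <- warp_spec(5, 8)
  # all-zero movie stays all-zero
  z <- stimulus_movie(array(0L, c(128, 128, 2)), grid, 1, "fixed", 8)
  expect_equal(sum(warp_movie(z, ws)$frames), 0)
  # a thin radial spoke at 30 deg keeps its angle (within one pixel)
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  th <- 30 * pi / 180
  X <- matrix(xs, 128, 128, byrow = TRUE); Y <- matrix(ys, 128, 128)
  r <- sqrt(X^2 + Y^2)
  perp <- abs(-sin(th) * X + cos(th) * Y)
  along <- cos(th) * X + sin(th) * Y
  spoke <- array(as.integer(perp <= grid$deg_per_px & along > 0.5 & r <= 8),
                 c(128, 128, 1))
  wm <- warp_movie(stimulus_movie(spoke, grid, 1, "fixed", 8), ws)
  act <- which(wm$frames[, , 1] == 1, arr.ind = TRUE)
  ang <- atan2(ys[act[, 1]], xs[act[, 2]])
  rr <- sqrt(xs[act[, 2]]^2 + ys[act[, 1]]^2)
  # angular tolerance of one pixel at each radius
  expect_true(all(abs(ang - th) <= atan2(1.5 * grid$deg_per_px, rr)))
  # a ring at the aperture edge maps onto itself
  ring <- array(as.integer(abs(r - 8) <= grid$deg_per_px), c(128, 128, 1))
  wr <- warp_movie(stimulus_movie(ring, grid, 1, "fixed", 8), ws)
  act_r <- which(wr$frames[, , 1] == 1, arr.ind = TRUE)
  rr2 <- sqrt(xs[act_r[, 2]]^2 + ys[act_r[, 1]]^2)
  expect_true(mean(abs(rr2 - 8)) <= 2 * grid$deg_per_px)
})

test_that("the identity-limit warp returns the input exactly", {
  pair <- local_stim_pair()
  wm <- warp_movie(pair$fixed, warp_spec(1e-8, 8))
  expect_identical(wm$frames, pair$fixed$frames)
  expect_equal(wm$label, "log")
})

test_that("warped peripheral bars are radially wider than foveal bars", {
  grid <- field_grid(256, rmax = 8)
  ws <- warp_spec(5, 8)
  sw <- sweep_spec(direction = 0, bar_width = 2, speed = 0.4, duration = 45)
  xs <- grid_xs(grid)
  mer <- abs(grid_ys(grid)) < 2 * grid$deg_per_px  # horizontal meridian rows
  radial_extent <- function(offset) {
    fr <- array(make_bar_frame(offset, sw, grid, 8), c(256, 256, 1))
    wm <- warp_movie(stimulus_movie(fr, grid, 1, "fixed", 8), ws)
    cols <- which(colSums(wm$frames[mer, , 1]) > 0 & xs >= 0)
    diff(range(xs[cols]))
  }
  fov <- radial_extent(1)   # bar occupying [0, 2] deg
  per <- radial_extent(7)   # bar occupying [6, 8] deg
  expect_gt(per, fov)
  # frozen expectations from the warp's closed form: the [0,2] bar appears
  # at [0, 0.306] deg, the [6,8] bar at [3.04, 8] deg
  expect_equal(fov, 0.30608790688704857, tolerance = 3 * grid$deg_per_px)
  expect_equal(per, 8 - 3.0405437428601194, tolerance = 3 * grid$deg_per_px)
})

test_that("preprocessing resamples to the exact target and rebinarizes", {
  pair <- local_stim_pair()
  pp <- preprocess_movie(pair$fixed, target_px = 32, target_frames = 61)
  expect_equal(dim(pp$frames), c(32, 32, 61))
  expect_true(all(pp$frames %in% c(0L, 1L)))
  expect_equal(n_frames(pp) * pp$frame_duration_s,
               n_frames(pair$fixed) * pair$fixed$frame_duration_s)
  # degrees covered is unchanged
  expect_equal(pp$grid$deg_per_px * 32, pair$fixed$grid$deg_per_px * 64)
  frac <- preprocess_movie(pair$fixed, 32, 61, binarize = FALSE)
  expect_true(all(frac$frames >= 0 & frac$frames <= 1))
  expect_true(any(frac$frames > 0 & frac$frames < 1))
  expect_error(preprocess_movie(pp, 64, 61), "upsampling")
})

test_that("downsampling an all-ones disc preserves its radius", {
  grid <- field_grid(320, rmax = 8)
  xs <- grid_xs(grid)
  r2 <- outer(grid_ys(grid)^2, xs^2, `+`)
  disc <- array(as.integer(r2 <= 6^2), c(320, 320, 4))
  m <- stimulus_movie(disc, grid, 1, "fixed", 8)
  pp <- preprocess_movie(m, 80, 4)
  # direct rasterization at the target resolution
  g2 <- field_grid(80, rmax = 8)
  direct <- as.integer(outer(grid_ys(g2)^2, grid_xs(g2)^2, `+`) <= 6^2)
  mismatch <- which(pp$frames[, , 1] != direct, arr.ind = TRUE)
  if (nrow(mismatch) > 0) {
    rr <- sqrt(grid_xs(g2)[mismatch[, 2]]^2 + grid_ys(g2)[mismatch[, 1]]^2)
    expect_true(all(abs(rr - 6) <= g2$deg_per_px))  # only edge pixels differ
  } else {
    succeed()
  }
})
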