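test_that("the Gaussian field has unit peak, correct falloff, and isotropy", {
  grid <- field_grid(101, deg_per_px = 0.1)
  # center a pRF exactly on a pixel center
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  prf <- prf_params(xs[61], ys[41], 0.7)
  G <- gaussian_field(prf, grid)
  expect_equal(G[41, 61], 1)
  # closed form at every pixel
  expected <- exp(-(outer(ys - prf$mu_y, xs - prf$mu_x,
                          function(y, x) x^2 + y^2)) / (2 * 0.7^2))
  expect_equal(G, expected, tolerance = 1e-12)
  # isotropy: equal steps in x and y from the center give equal values
  expect_equal(G[41, 66], G[36, 61], tolerance = 1e-12)
  expect_error(prf_params(0, 0, 0), "sigma")
})

test_that("predict_timecourse matches the brute-force double loop", {
  grid <- field_grid(16, rmax = 8)
  sw <- sweep_spec(direction = 45, bar_width = 2, speed = 1.5, duration = 12)
  frames <- make_sweep(sw, grid, 8, 1)
  m <- stimulus_movie(frames, grid, 1, "fixed", 8)
  hrf <- hrf_params()
  for (prf in list(prf_params(0.5, -0.3, 1.2), prf_params(-3, 2, 0.6))) {
    expect_equal(predict_timecourse(m, prf, hrf)$values,
                 brute_force_predict(m, prf, hrf), tolerance = 1e-10)
  }
  # fractional-coverage path
  mf <- m
  mf$frames <- m$frames * 0.6
  prf <- prf_params(1, 1, 1)
  expect_equal(predict_timecourse(mf, prf, hrf)$values,
               brute_force_predict(mf, prf, hrf), tolerance = 1e-10)
  expect_equal(predict_timecourse(mf, prf, hrf)$values,
               0.6 * predict_timecourse(m, prf, hrf)$values,
               tolerance = 1e-10)
})

test_that("degenerate stimuli behave as expected", {
  grid <- field_grid(32, rmax = 8)
  z <- stimulus_movie(array(0L, c(32, 32, 20)), grid, 1, "fixed", 8)
  hrf <- hrf_params()
  expect_equal(predict_timecourse(z, prf_params(0, 0, 1), hrf)$values,
               numeric(20))
  # a pRF far outside the aperture is silent relative to a centered one
  pair <- local_stim_pair()
  far <- predict_timecourse(pair$fixed, prf_params(50, 0, 1), hrf)$values
  ctr <- predict_timecourse(pair$fixed, prf_params(0, 0, 1), hrf)$values
  expect_lte(max(abs(far)), 1e-6 * max(abs(ctr)))
})

test_that("prediction is linear in the stimulus", {
  grid <- field_grid(32, rmax = 8)
  xs <- grid_xs(grid)
  # two disjoint apertures (left and right half-discs)
  r2 <- outer(grid_ys(grid)^2, xs^2, `+`)
  left <- array(as.integer(r2 <= 36 & rep(xs < 0, each = 32)), c(32, 32, 15))
  right <- array(as.integer(r2 <= 36 & rep(xs > 0, each = 32)), c(32, 32, 15))
  hrf <- hrf_params()
  prf <- prf_params(0.7, -0.2, 2)
  p_l <- predict_timecourse(stimulus_movie(left, grid, 1, "fixed", 8), prf, hrf)
  p_r <- predict_timecourse(stimulus_movie(right, grid, 1, "fixed", 8), prf, hrf)
  p_lr <- predict_timecourse(stimulus_movie(left + right, grid, 1, "fixed", 8),
                             prf, hrf)
  expect_equal(p_lr$values, p_l$values + p_r$values, tolerance = 1e-10)
})

test_that("overlap traces are unimodal and shift-covariant on cardinal sweeps", {
  grid <- field_grid(64, rmax = 8)
  sw <- sweep_spec(direction = 0, bar_width = 2, speed = 0.4, duration = 45)
  frames <- make_sweep(sw, grid, 8, 1)
  m <- stimulus_movie(frames, grid, 1, "fixed", 8)
  sp <- logprf:::.stim_sparse(m)
  n_local_maxima <- function(v) {
    act <- which(v > 1e-9 * max(v))
    sum(diff(act) > 1)  # gaps would split the single crossing
  }
  for (mu in list(c(0, 0), c(2, 1), c(-4, -2))) {
    ov <- logprf:::.overlap_matrix(sp, mu[1], mu[2], 0.4)[, 1]
    expect_equal(n_local_maxima(ov), 0)  # single contiguous crossing
  }
  # translating the center along the sweep axis shifts the peak by d / speed
  ov0 <- logprf:::.overlap_matrix(sp, -2, 0.5, 0.3)[, 1]
  ov1 <- logprf:::.overlap_matrix(sp, 0, 0.5, 0.3)[, 1]
  expect_equal(which.max(ov1) - which.max(ov0), 2 / 0.4, tolerance = 1)
})
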