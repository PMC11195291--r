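test_that("the ground-truth grid has the stated cardinality and sizes", {
  g <- make_prf_grid(sim_grid_spec())
  expect_equal(nrow(g), 4800)                     # 24 angles x 200 eccs
  expect_equal(length(unique(g$angle_deg)), 24)
  expect_equal(length(unique(round(g$ecc, 10))), 200)
  expect_equal(min(g$sigma), 0.15 * 0.01 + 0.1)   # 0.1015 at ecc_min
  expect_equal(range(g$ecc), c(0.01, 8))
  # the size relation evaluated on the grid
  expect_equal(g$sigma, 0.15 * g$ecc + 0.1)
  expect_equal(sigma_at(size_ecc_relation(), 1), 0.25)
  # cardinality is n_angles x ecc_steps for arbitrary specs
  for (p in list(c(45, 50), c(90, 7), c(30, 11))) {
    s <- sim_grid_spec(angle_step = p[1], ecc_steps = p[2])
    expect_equal(nrow(make_prf_grid(s)),
                 length(seq(0, 345, by = p[1])) * p[2])
  }
  # deterministic, angle-major ordering
  expect_identical(make_prf_grid(sim_grid_spec()), make_prf_grid(sim_grid_spec()))
  g2 <- make_prf_grid(sim_grid_spec(angle_step = 90, ecc_steps = 3))
  expect_equal(g2$angle_deg, rep(c(0, 90, 180, 270), each = 3))
})

test_that("simulated datasets are seeded, calibrated, and exact at sd = 0", {
  pair <- local_stim_pair()
  hrf <- hrf_params()
  grid <- make_prf_grid(sim_grid_spec(angle_step = 90, ecc_steps = 5))
  ds0 <- simulate_dataset(grid, pair$fixed, hrf, noise_spec(sd = 0, n_reps = 2))
  expect_equal(ds0$timecourses[, seq_len(nrow(grid))], ds0$noiseless)
  expect_equal(ds0$timecourses[, nrow(grid) + seq_len(nrow(grid))],
               ds0$noiseless)
  # peak normalization
  expect_equal(unname(apply(abs(ds0$noiseless), 2, max)),
               rep(1, nrow(grid)))
  # seeded reproducibility
  n1 <- simulate_dataset(grid, pair$fixed, hrf, noise_spec(n_reps = 2, rng_seed = 9))
  n2 <- simulate_dataset(grid, pair$fixed, hrf, noise_spec(n_reps = 2, rng_seed = 9))
  expect_identical(n1$timecourses, n2$timecourses)
  n3 <- simulate_dataset(grid, pair$fixed, hrf, noise_spec(n_reps = 2, rng_seed = 10))
  expect_false(identical(n1$timecourses, n3$timecourses))
  # snr default: sd = peak / snr = 1/3 after normalization
  expect_equal(n1$sd, 1 / 3)
})

test_that("the realized noise standard deviation matches the specification", {
  pair <- local_stim_pair()
  grid <- make_prf_grid(sim_grid_spec(angle_step = 45, ecc_steps = 10))
  ds <- simulate_dataset(grid, pair$fixed, hrf_params(),
                         noise_spec(sd = 0.5, n_reps = 40, rng_seed = 3))
  resid <- ds$timecourses - ds$noiseless[, rep(seq_len(nrow(grid)), 40)]
  expect_equal(sd(resid), 0.5, tolerance = 0.01 * 0.5)
})

test_that("recovery analysis computes bias, RMSE, and retention per bin", {
  truth <- data.frame(unit_id = 1:60,
                      sigma = rep(seq(0.2, 1.2, length.out = 20), 3),
                      ecc = rep(exp(seq(log(0.02), log(7), length.out = 20)), 3))
  fits <- data.frame(sigma = truth$sigma, retained = TRUE)
  r0 <- recovery_analysis(list(x = fits), truth, bins = ecc_bins(6))
  expect_true(all(r0$bias[r0$n > 0] == 0))
  expect_true(all(r0$rmse[r0$n > 0] == 0))
  expect_true(all(r0$retention[r0$n > 0] == 1))
  # additive bias shows up as-is in every bin
  fits2 <- data.frame(sigma = truth$sigma + 0.2, retained = TRUE)
  r2 <- recovery_analysis(list(x = fits2), truth, bins = ecc_bins(6))
  expect_equal(r2$bias[r2$n > 0], rep(0.2, sum(r2$n > 0)), tolerance = 1e-12)
  # non-retained units are excluded from accuracy but counted in retention
  fits3 <- fits
  fits3$retained[truth$ecc < 0.1] <- FALSE
  r3 <- recovery_analysis(list(x = fits3), truth, bins = ecc_bins(6))
  expect_true(any(r3$retention < 1, na.rm = TRUE))
  # empty bins are reported as NA rows, not dropped
  keep <- truth$ecc > 1
  r4 <- recovery_analysis(list(x = fits[keep, ]), truth[keep, ],
                          bins = ecc_bins(8))
  expect_equal(nrow(r4), 8)
  expect_true(any(r4$n == 0 & is.na(r4$bias)))
})
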