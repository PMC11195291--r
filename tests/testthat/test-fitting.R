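test_that("the correlation objective is affine-invariant and NA-safe", {
  x <- with_seed(41, rnorm(50))
  expect_equal(prf_objective(x, x), 1)
  expect_equal(prf_objective(x, -x), -1)
  expect_equal(prf_objective(3 * x + 7, x), 1)
  expect_true(is.na(prf_objective(rep(1, 50), x)))
  expect_true(is.na(prf_objective(x, rep(0, 50))))
  expect_error(prf_objective(x, x[-1]), "length")
})

test_that("grid search returns the exact generating seed and beats brute force", {
  pair <- local_stim_pair()
  hrf <- hrf_params()
  ctx <- fit_context(pair$fixed, hrf)
  spec <- grid_search_spec(center_steps = 5, sigma_steps = 5)
  seeds <- grid_seeds(spec)
  expect_equal(nrow(seeds), 5 * 5 * 5)
  expect_equal(nrow(grid_seeds(grid_search_spec())), 8000)
  # noiseless data generated from an on-grid seed is recovered exactly
  truth_i <- 47
  tc <- predict_timecourse(pair$fixed,
                           prf_params(seeds$mu_x[truth_i], seeds$mu_y[truth_i],
                                      seeds$sigma[truth_i]), hrf)
  gs <- grid_search(tc, spec = spec, ctx = ctx)
  expect_equal(gs$index, truth_i)
  expect_equal(gs$correlation, 1, tolerance = 1e-9)
  # exhaustive naive loop over the reduced grid agrees
  d <- with_seed(42, tc$values + rnorm(length(tc$values), sd = 2))
  gs2 <- grid_search(d, spec = spec, ctx = ctx)
  naive <- vapply(seq_len(nrow(seeds)), function(i) {
    p <- predict_timecourse(pair$fixed,
                            prf_params(seeds$mu_x[i], seeds$mu_y[i],
                                       seeds$sigma[i]), hrf)
    prf_objective(d, p)
  }, 0)
  expect_equal(gs2$index, which.max(naive))
  expect_equal(gs2$correlation, max(naive), tolerance = 1e-8)
  expect_true(all(gs2$correlation >= naive - 1e-12))
})

test_that("refinement recovers off-grid truth and never falls below its seed", {
  pair <- local_stim_pair()
  hrf <- hrf_params()
  for (lab in c("fixed", "log")) {
    ctx <- fit_context(pair[[lab]], hrf)
    truth <- prf_params(1.3, -0.7, 0.5)
    tc <- predict_timecourse(pair[[lab]], truth, hrf)
    gs <- grid_search(tc, spec = grid_search_spec(center_steps = 10,
                                                  sigma_steps = 10), ctx = ctx)
    fit <- refine_fit(tc, seed = gs$prf, ctx = ctx)
    expect_equal(fit$prf$mu_x, truth$mu_x, tolerance = 0.05)
    expect_equal(fit$prf$mu_y, truth$mu_y, tolerance = 0.05)
    expect_equal(fit$prf$sigma, truth$sigma, tolerance = 0.05 * truth$sigma)
    expect_gte(fit$correlation, gs$correlation - 1e-12)
  }
})

test_that("refinement keeps sigma positive and improves noisy seeds", {
  pair <- local_stim_pair()
  hrf <- hrf_params()
  ctx <- fit_context(pair$fixed, hrf)
  spec <- grid_search_spec(center_steps = 6, sigma_steps = 4)
  truth <- prf_params(0.4, 0.2, 0.15)
  base <- predict_timecourse(pair$fixed, truth, hrf)$values
  for (s in 1:5) {
    d <- with_seed(100 + s, base / max(abs(base)) + rnorm(length(base), sd = 0.4))
    gs <- grid_search(d, spec = spec, ctx = ctx)
    fit <- refine_fit(d, seed = gs$prf, ctx = ctx)
    expect_gte(fit$correlation, gs$correlation - 1e-12)
    expect_gt(fit$prf$sigma, 0)
  }
})

test_that("zero-variance units are flagged invalid, not fatal", {
  pair <- local_stim_pair()
  hrf <- hrf_params()
  d <- cbind(rep(1, n_frames(pair$fixed)),
             predict_timecourse(pair$fixed, prf_params(1, 1, 1), hrf)$values)
  fits <- fit_prfs(d, pair$fixed, hrf,
                   grid = grid_search_spec(center_steps = 6, sigma_steps = 4))
  expect_true(is.na(fits$correlation[1]))
  expect_false(fits$retained[1])
  expect_false(is.na(fits$correlation[2]))
})

test_that("fit_prfs is deterministic", {
  pair <- local_stim_pair()
  hrf <- hrf_params()
  base <- predict_timecourse(pair$fixed, prf_params(2, -1, 0.6), hrf)$values
  d <- with_seed(55, cbind(base + rnorm(length(base), sd = max(base) / 3),
                           base + rnorm(length(base), sd = max(base) / 3)))
  spec <- grid_search_spec(center_steps = 8, sigma_steps = 5)
  f1 <- fit_prfs(d, pair$fixed, hrf, grid = spec)
  f2 <- fit_prfs(d, pair$fixed, hrf, grid = spec)
  expect_identical(f1, f2)
})

test_that("retention filters apply the strict printed rules", {
  res <- data.frame(eccentricity = c(9, 2, 2, 2, 8, 2),
                    sigma = c(1, 0.04, 1, 1, 1, 0.05),
                    variance_explained = c(0.5, 0.5, 0.11, 0.10, 0.5, 0.5))
  out <- apply_filters(res, retention_rule())
  expect_equal(out$retained, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # NA goodness of fit is never retained
  res$variance_explained[3] <- NA
  expect_false(apply_filters(res, retention_rule())$retained[3])
})

test_that("HRF estimation recovers the generating HRF and obeys selection", {
  pair <- local_stim_pair()
  truth_hrf <- hrf_params()
  prfs <- data.frame(mu_x = c(1.5, -2, 0.5, 3, -1, 2.5),
                     mu_y = c(0.5, 1, -2, -0.5, 2.2, 1.4),
                     sigma = c(0.4, 0.6, 0.5, 0.8, 0.55, 0.7))
  sp <- logprf:::.stim_sparse(pair$fixed)
  kern <- hrf_kernel(truth_hrf, sp$dt)
  D <- logprf:::.predict_matrix(sp, prfs$mu_x, prfs$mu_y, prfs$sigma, kern)
  # noiseless data, perturbed initial HRF: recover within 5 percent
  init <- hrf_params(delta = 0.2, alpha1 = 6.8, alpha2 = 14.5,
                     beta1 = 1.15, beta2 = 0.9, ratio = 5)
  est <- estimate_hrf(D, prfs, pair$fixed, init = init, select_frac = 0.5)
  expect_equal(attr(est, "n_qualifying"), 6)
  expect_equal(attr(est, "n_selected"), ceiling(0.5 * 6))
  for (nm in c("alpha1", "alpha2", "beta1", "beta2", "ratio"))
    expect_equal(est[[nm]], truth_hrf[[nm]], tolerance = 0.05,
                 label = sprintf("estimated %s", nm))
  expect_lt(abs(est$delta - truth_hrf$delta), 0.25)
  # single-unit selection: the median is that unit's fit
  est1 <- estimate_hrf(D[, 3, drop = FALSE], prfs[3, ], pair$fixed,
                       init = init, select_frac = 1)
  expect_equal(attr(est1, "n_selected"), 1L)
  # no qualifying units: fall back to init with a warning
  flat <- matrix(rep(seq_len(nrow(D)), 2), ncol = 2)
  expect_warning(
    est0 <- estimate_hrf(flat, prfs[1:2, ], pair$fixed, init = init),
    "threshold")
  expect_equal(unclass(est0)[1:6], unclass(init)[1:6])
})

test_that("alternate_fit reduces to a single pass with a fixed HRF", {
  pair <- local_stim_pair()
  hrf <- hrf_params()
  base <- cbind(
    predict_timecourse(pair$fixed, prf_params(1.5, 0.5, 0.4), hrf)$values,
    predict_timecourse(pair$fixed, prf_params(-2, 1, 0.6), hrf)$values)
  spec <- grid_search_spec(center_steps = 8, sigma_steps = 5)
  af <- alternate_fit(base, pair$fixed, init_hrf = hrf, grid = spec,
                      fit_hrf = FALSE)
  direct <- fit_prfs(base, pair$fixed, hrf, grid = spec)
  expect_identical(af$fits, direct)
  expect_equal(unclass(af$hrf)[1:6], unclass(hrf)[1:6])
})

test_that("alternating estimation is coordinate ascent on a single unit", {
  pair <- local_stim_pair()
  truth_hrf <- hrf_params(delta = 0.4, alpha1 = 5.5)
  d <- predict_timecourse(pair$fixed, prf_params(1.5, 0.5, 0.5),
                          truth_hrf)$values
  spec <- grid_search_spec(center_steps = 8, sigma_steps = 5)
  af <- alternate_fit(matrix(d, ncol = 1), pair$fixed,
                      init_hrf = hrf_params(), grid = spec, n_iter = 3,
                      select_frac = 1, min_ve = 0.1)
  # per-iteration grid-search objective never decreases
  expect_true(all(diff(af$history) >= -1e-9))
  expect_gte(af$fits$correlation[1], max(af$history) - 1e-9)
})
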