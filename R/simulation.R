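# Parameter-recovery simulation: ground-truth pRF grids spanning the
# visual field, noisy synthetic BOLD for fixed- and log-bar stimuli, and
# the recovery analysis comparing estimated to true pRF size.

#' Linear size-eccentricity relation
#'
#' Ground-truth pRF size as a function of eccentricity:
#' `sigma = slope * ecc + intercept` (defaults 0.15 and 0.1 deg, a V1-like
#' relation).
#'
#' @param slope Degrees of sigma per degree of eccentricity.
#' @param intercept Degrees.
#' @return An object of class `size_ecc_relation`.
#' @export
size_ecc_relation <- function(slope = 0.15, intercept = 0.1) {
  .check_num(slope, "slope", nonneg = TRUE)
  .check_num(intercept, "intercept", positive = TRUE)
  structure(list(slope = slope, intercept = intercept),
            class = "size_ecc_relation")
}

#' Evaluate a size-eccentricity relation
#'
#' @param relation A [size_ecc_relation()].
#' @param ecc Eccentricities in degrees.
#' @return pRF sizes in degrees.
#' @export
sigma_at <- function(relation, ecc) {
  stopifnot(inherits(relation, "size_ecc_relation"))
  relation$slope * ecc + relation$intercept
}

#' Ground-truth simulation grid specification
#'
#' Defaults reproduce the full simulation grid: polar angles 0 to 345 deg
#' in 15 deg steps (24 angles) crossed with 200 log-spaced eccentricities
#' from 0.01 to 8 deg -- 4800 unique pRF locations, sizes from the
#' size-eccentricity relation.
#'
#' @param angle_start,angle_stop,angle_step Polar angle grid, degrees.
#' @param ecc_min,ecc_max Eccentricity range, degrees.
#' @param ecc_steps Number of logarithmically spaced eccentricities.
#' @param relation A [size_ecc_relation()].
#' @return An object of class `sim_grid_spec`.
#' @export
sim_grid_spec <- function(angle_start = 0, angle_stop = 345, angle_step = 15,
                          ecc_min = 0.01, ecc_max = 8, ecc_steps = 200,
                          relation = size_ecc_relation()) {
  stopifnot(angle_step > 0, ecc_steps >= 2, ecc_min > 0, ecc_min < ecc_max)
  structure(list(angle_start = angle_start, angle_stop = angle_stop,
                 angle_step = angle_step, ecc_min = ecc_min,
                 ecc_max = ecc_max, ecc_steps = as.integer(ecc_steps),
                 relation = relation),
            class = "sim_grid_spec")
}

#' Build the ground-truth pRF grid
#'
#' Cartesian product of the angle and eccentricity grids, angle-major
#' (all eccentricities of the first angle, then the next angle), converted
#' to Cartesian centers with sizes from the relation. Deterministic.
#'
#' @param spec A [sim_grid_spec()].
#' @return Data frame with `prf_id`, `angle_deg`, `ecc`, `mu_x`, `mu_y`,
#'   `sigma`; `n_angles * ecc_steps` rows (4800 at the defaults).
#' @export
make_prf_grid <- function(spec = sim_grid_spec()) {
  stopifnot(inherits(spec, "sim_grid_spec"))
  angles <- seq(spec$angle_start, spec$angle_stop, by = spec$angle_step)
  eccs <- exp(seq(log(spec$ecc_min), log(spec$ecc_max),
                  length.out = spec$ecc_steps))
  g <- expand.grid(ecc = eccs, angle_deg = angles,
                   KEEP.OUT.ATTRS = FALSE)[, c("angle_deg", "ecc")]
  th <- g$angle_deg * pi / 180
  data.frame(prf_id = seq_len(nrow(g)), angle_deg = g$angle_deg,
             ecc = g$ecc, mu_x = g$ecc * cos(th), mu_y = g$ecc * sin(th),
             sigma = sigma_at(spec$relation, g$ecc))
}

#' Noise specification for simulated time courses
#'
#' IID Gaussian noise. The default noise level is stated as a time-course
#' signal-to-noise ratio: noiseless predictions are peak-normalized per
#' unit and noise with `sd = peak / snr` is added, so `snr = 3` means the
#' peak response is three noise standard deviations.
#'
#' @param sd Noise standard deviation in prediction units; when `NULL`
#'   (default) it is derived from `snr` at simulation time.
#' @param snr Peak-signal-to-noise ratio used when `sd` is `NULL`.
#' @param n_reps Number of noisy replicates of the grid.
#' @param rng_seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd = NULL, snr = 3, n_reps = 100, rng_seed = 1L) {
  if (!is.null(sd)) .check_num(sd, "sd", nonneg = TRUE)
  .check_num(snr, "snr", positive = TRUE)
  stopifnot(n_reps >= 1)
  structure(list(sd = sd, snr = snr, n_reps = as.integer(n_reps),
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

#' Simulate a noisy dataset from a ground-truth pRF grid
#'
#' Noiseless time courses are generated with the forward model (identical
#' to [predict_timecourse()] per unit), peak-normalized per unit when
#' `normalize = TRUE`, replicated `n_reps` times, and perturbed with IID
#' Gaussian noise. Seeded and reproducible: the same inputs give an
#' identical dataset.
#'
#' @param grid Data frame from [make_prf_grid()] (columns `mu_x`, `mu_y`,
#'   `sigma`).
#' @param stim A preprocessed [stimulus_movie()].
#' @param hrf An [hrf_params()] object.
#' @param noise A [noise_spec()].
#' @param normalize Peak-normalize each noiseless time course (default
#'   `TRUE`; units with an all-zero response are left at zero and noted in
#'   the truth table).
#' @param span HRF kernel support, seconds.
#' @return List with `timecourses` (matrix, time x `nrow(grid) * n_reps`),
#'   `truth` (one row per column: `unit_id`, `prf_id`, `rep`, truth
#'   parameters, `peak`), `noiseless` (time x `nrow(grid)`), `sd`, `dt`.
#' @export
simulate_dataset <- function(grid, stim, hrf, noise = noise_spec(),
                             normalize = TRUE, span = 40) {
  stopifnot(inherits(stim, "stimulus_movie"), inherits(hrf, "hrf_params"),
            inherits(noise, "noise_spec"))
  sp <- .stim_sparse(stim)
  kern <- hrf_kernel(hrf, sp$dt, span)
  P <- .predict_matrix(sp, grid$mu_x, grid$mu_y, grid$sigma, kern, 8)
  peak <- apply(abs(P), 2, max)
  if (normalize) {
    nzc <- peak > 0
    P[, nzc] <- sweep(P[, nzc, drop = FALSE], 2, peak[nzc], "/")
  }
  sd_use <- noise$sd %||%
    (if (normalize) 1 / noise$snr else stats::median(peak[peak > 0]) / noise$snr)
  nr <- noise$n_reps
  np <- nrow(grid)
  Y <- P[, rep(seq_len(np), nr), drop = FALSE]
  if (sd_use > 0) {
    Y <- Y + with_seed(noise$rng_seed,
                       matrix(rnorm(length(Y), sd = sd_use), nrow(Y)))
  }
  truth <- data.frame(unit_id = seq_len(np * nr),
                      prf_id = rep(grid$prf_id %||% seq_len(np), nr),
                      rep = rep(seq_len(nr), each = np),
                      mu_x = rep(grid$mu_x, nr), mu_y = rep(grid$mu_y, nr),
                      sigma = rep(grid$sigma, nr),
                      ecc = rep(sqrt(grid$mu_x^2 + grid$mu_y^2), nr),
                      peak = rep(peak, nr))
  list(timecourses = Y, truth = truth, noiseless = P, sd = sd_use,
       dt = sp$dt)
}

#' Log-spaced eccentricity bin edges
#'
#' @param n Number of bins.
#' @param lo,hi Range in degrees.
#' @return Numeric vector of `n + 1` edges.
#' @export
ecc_bins <- function(n = 16, lo = 0.01, hi = 8) {
  exp(seq(log(lo), log(hi), length.out = n + 1))
}

#' Recovery analysis of simulated pRF fits
#'
#' Joins fitted and true parameters by unit, restricts accuracy statistics
#' to retained fits, and summarizes per eccentricity bin and stimulus
#' label: mean true and recovered sigma, bias (`mean(est - truth)`), RMSE,
#' and the retention fraction. Empty bins are reported as `NA` rows, not
#' dropped.
#'
#' @param fits [fit_prfs()] table (or a named list of tables, one per
#'   stimulus label, e.g. `list(fixed = ..., log = ...)`).
#' @param truth Truth table from [simulate_dataset()].
#' @param bins Eccentricity bin edges (default `ecc_bins()`), applied to
#'   the true eccentricity.
#' @return Data frame of class `recovery_report` with one row per
#'   (label, bin).
#' @export
recovery_analysis <- function(fits, truth, bins = ecc_bins()) {
  if (is.data.frame(fits)) fits <- list(stimulus = fits)
  rows <- list()
  for (lab in names(fits)) {
    f <- fits[[lab]]
    stopifnot(nrow(f) == nrow(truth))
    idx <- findInterval(truth$ecc, bins, rightmost.closed = TRUE)
    for (b in seq_len(length(bins) - 1)) {
      inb <- which(idx == b)
      ret <- inb[f$retained[inb] %in% TRUE]
      err <- f$sigma[ret] - truth$sigma[ret]
      rows[[length(rows) + 1]] <- data.frame(
        label = lab, bin = b, ecc_lo = bins[b], ecc_hi = bins[b + 1],
        n = length(inb), n_retained = length(ret),
        retention = if (length(inb)) length(ret) / length(inb) else NA_real_,
        truth_sigma = if (length(ret)) mean(truth$sigma[ret]) else NA_real_,
        est_sigma = if (length(ret)) mean(f$sigma[ret]) else NA_real_,
        bias = if (length(ret)) mean(err) else NA_real_,
        rmse = if (length(ret)) sqrt(mean(err^2)) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", class(out))
  out
}

#' Simulation profile settings
#'
#' `"full"` reproduces the published-scale simulation (24 angles x 200
#' eccentricities, 100 noisy replicates, 20x20x20 seed grid, 540 px render
#' at 10 fps) and is computationally heavy. `"fast"` is the desk-scale
#' profile: 45 deg angle steps, 50 eccentricity steps, 10 replicates, a
#' 10x10x10 seed grid, and a 216 px render at 2 fps. Both preprocess to
#' 108 x 108 x 366.
#'
#' @param profile `"fast"` or `"full"`.
#' @return Named list of settings.
#' @export
sim_profile <- function(profile = c("fast", "full")) {
  profile <- match.arg(profile)
  if (profile == "fast") {
    list(name = "fast",
         grid = sim_grid_spec(angle_step = 45, ecc_steps = 50),
         noise = noise_spec(n_reps = 10),
         search = grid_search_spec(center_steps = 10, sigma_steps = 10),
         render_px = 216, render_fps = 2)
  } else {
    list(name = "full",
         grid = sim_grid_spec(),
         noise = noise_spec(n_reps = 100),
         search = grid_search_spec(),
         render_px = 540, render_fps = 10)
  }
}

#' Run the full parameter-recovery experiment
#'
#' Builds fixed- and log-bar stimuli, simulates noisy datasets from the
#' ground-truth grid with a shared HRF, fits every unit for each stimulus
#' type, and returns the per-bin recovery report. The fit uses the same
#' (known) HRF that generated the data unless `fit_hrf = TRUE`, in which
#' case the alternating HRF estimation is run first.
#'
#' @param seed Integer seed driving sweep order and noise.
#' @param profile `"fast"` or `"full"` (see [sim_profile()]).
#' @param hrf Generating [hrf_params()].
#' @param warp A [warp_spec()].
#' @param rule A [retention_rule()].
#' @param fit_hrf Estimate the HRF during fitting instead of using the
#'   generating HRF (slower; default `FALSE`).
#' @param bins Eccentricity bin edges for the report.
#' @return List with `report` (the [recovery_analysis()] table), `fits`
#'   (named list of fit tables), `truth`, `stims`, and `settings`.
#' @export
recovery_experiment <- function(seed = 1, profile = "fast",
                                hrf = hrf_params(), warp = warp_spec(),
                                rule = retention_rule(), fit_hrf = FALSE,
                                bins = ecc_bins()) {
  prof <- sim_profile(profile)
  run <- run_spec(frame_rate_hz = prof$render_fps, rng_seed = seed)
  stims <- list(
    fixed = build_stimulus("fixed", warp, run, render_px = prof$render_px),
    log = build_stimulus("log", warp, run, render_px = prof$render_px))
  grid <- make_prf_grid(prof$grid)
  noise <- prof$noise
  fits <- list()
  truth <- NULL
  for (lab in names(stims)) {
    noise_lab <- noise
    # distinct noise stream per stimulus type, derived from the main seed
    noise_lab$rng_seed <- as.integer((seed + 7919L * match(lab, names(stims))) %% .Machine$integer.max)
    ds <- simulate_dataset(grid, stims[[lab]], hrf, noise_lab)
    truth <- ds$truth
    if (fit_hrf) {
      af <- alternate_fit(ds$timecourses, stims[[lab]], init_hrf = hrf,
                          grid = prof$search, rule = rule)
      fits[[lab]] <- af$fits
    } else {
      fits[[lab]] <- fit_prfs(ds$timecourses, stims[[lab]], hrf,
                              grid = prof$search, rule = rule)
    }
  }
  list(report = recovery_analysis(fits, truth, bins), fits = fits,
       truth = truth, stims = stims,
       settings = list(profile = prof$name, seed = seed))
}
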