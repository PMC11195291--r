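# Independent oracles: naive reference implementations kept deliberately
# separate from the package's computation paths.

# per-pixel, per-frame double loop forward model with O(n^2) convolution
brute_force_predict <- function(movie, prf, hrf, span = 40) {
  xs <- grid_xs(movie$grid)
  ys <- grid_ys(movie$grid)
  d <- dim(movie$frames)
  overlap <- numeric(d[3])
  for (t in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        v <- movie$frames[i, j, t]
        if (v != 0) {
          s <- s + v * exp(-((xs[j] - prf$mu_x)^2 + (ys[i] - prf$mu_y)^2) /
                             (2 * prf$sigma^2))
        }
      }
    }
    overlap[t] <- s
  }
  brute_force_conv(overlap, hrf_curve(hrf, seq(0, span, by = movie$frame_duration_s)))
}

# direct O(n^2) causal truncated convolution sum
brute_force_conv <- function(x, k) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, length(k)))) {
      y[i] <- y[i] + x[i - j + 1] * k[j]
    }
  }
  y
}

# Spearman correlation from the rank formula with midranks
brute_force_spearman <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  num / sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# shared small stimulus pair: 64 x 64 px, four 20 s full-traverse sweeps
# (two cardinal, two diagonal), 1 fps, small blanks; built once per test run
local_stim_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sweeps <- lapply(c(0, 90, 45, 225), sweep_spec,
                       bar_width = 2, speed = 0.9, duration = 20)
      run <- run_spec(sweeps = sweeps, pre_blank_s = 2, post_blank_s = 4,
                      frame_rate_hz = 1)
      grid <- field_grid(64, rmax = 8)
      fixed <- assemble_run(run, grid, 8)
      cache <<- list(fixed = fixed, log = warp_movie(fixed, warp_spec(5, 8)))
    }
    cache
  }
})
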