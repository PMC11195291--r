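# Plain-text and serialized I/O. Time-course matrices and fit tables
# travel as TSV with a JSON sidecar carrying sampling metadata; movies are
# serialized as RDS with a JSON sidecar (no NIfTI-capable package is
# assumed to be available).

.sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a time-course matrix as TSV
#'
#' Columns are units (`unit_1`, ...), rows are time points; the sampling
#' interval is stored in a `<path>.json` sidecar.
#'
#' @param x Numeric matrix (time x units).
#' @param path Output TSV path.
#' @param dt Seconds per sample.
#' @return `write_timecourses_tsv()` returns `path` invisibly;
#'   `read_timecourses_tsv()` returns the matrix with attribute `dt`.
#' @export
write_timecourses_tsv <- function(x, path, dt) {
  x <- as.matrix(x)
  colnames(x) <- paste0("unit_", seq_len(ncol(x)))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(dt = dt, n_time = nrow(x), n_units = ncol(x)),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timecourses_tsv
#' @export
read_timecourses_tsv <- function(path) {
  x <- as.matrix(read.delim(path, check.names = FALSE))
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    attr(x, "dt") <- meta$dt
  }
  x
}

#' Write / read a pRF fit table as TSV
#'
#' @param fits Data frame from [fit_prfs()].
#' @param path TSV path.
#' @return `write_fits_tsv()` returns `path` invisibly; `read_fits_tsv()`
#'   the data frame.
#' @export
write_fits_tsv <- function(fits, path) {
  write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fits_tsv
#' @export
read_fits_tsv <- function(path) read.delim(path)

#' Export an HRF curve as TSV
#'
#' @param params An [hrf_params()] object.
#' @param path TSV path.
#' @param dt,span Sampling interval and support, seconds.
#' @return `path`, invisibly.
#' @export
write_hrf_tsv <- function(params, path, dt = 0.1, span = 40) {
  t <- seq(0, span, by = dt)
  write.table(data.frame(t = t, h = hrf_curve(params, t)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a stimulus movie
#'
#' The movie is serialized as RDS; a JSON sidecar records the calibration
#' (deg/px, frame duration, label, rmax) for other tools.
#'
#' @param movie A [stimulus_movie()].
#' @param path Output `.rds` path.
#' @return `save_movie()` returns `path` invisibly; `load_movie()` the
#'   movie.
#' @export
save_movie <- function(movie, path) {
  stopifnot(inherits(movie, "stimulus_movie"))
  saveRDS(movie, path)
  d <- dim(movie$frames)
  jsonlite::write_json(
    list(height_px = d[1], width_px = d[2], n_frames = d[3],
         deg_per_px = movie$grid$deg_per_px,
         frame_duration_s = movie$frame_duration_s,
         label = movie$label, rmax = movie$rmax),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_movie
#' @export
load_movie <- function(path) {
  movie <- readRDS(path)
  stopifnot(inherits(movie, "stimulus_movie"))
  movie
}
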