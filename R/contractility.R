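#' Whole-frame pixel-velocity trace of a motion movie
#'
#' Runs the shared Horn-Schunck core on every consecutive frame pair of a
#' phase-contrast-like movie and reduces each field to the mean vector
#' magnitude over the whole frame, converted to um/s. Beating appears as
#' a train of speed peaks: one per contraction stroke and one per
#' relaxation stroke.
#'
#' Frames are rescaled to unit dynamic range before flow estimation, so
#' the measurement is invariant to illumination offset and gain, and the
#' smoothness weight `alpha` is expressed relative to unit contrast. The
#' default `alpha = 0.1` suits densely textured phase-contrast images,
#' where brightness constancy is informative at nearly every pixel and
#' only weak regularization is needed; heavier smoothing biases the
#' speed of textured motion towards zero.
#'
#' @param movie a `cw_movie` (>= 2 frames) with pixel size and frame rate
#'   set.
#' @param alpha,n_iter,tol Horn-Schunck settings.
#' @return a `velocity_trace`: list with `time_ms` (midpoint of each
#'   frame pair) and `speed_um_s`, both of length `n_frames - 1`.
#' @export
velocity_trace <- function(movie, alpha = 0.1, n_iter = 200, tol = 1e-6) {
  stopifnot(inherits(movie, "cw_movie"))
  nf <- n_frames(movie)
  if (nf < 2) stop("velocity trace needs at least 2 frames")
  fr <- movie$frames
  rngf <- max(fr) - min(fr)
  if (rngf > 0) fr <- (fr - min(fr)) / rngf
  speed <- vapply(seq_len(nf - 1), function(t) {
    f <- horn_schunck(fr[, , t], fr[, , t + 1],
                      alpha = alpha, n_iter = n_iter, tol = tol)
    mean(sqrt(f$u^2 + f$v^2))
  }, numeric(1)) * movie$pixel_size * movie$frame_rate
  dt_ms <- 1000 / movie$frame_rate
  structure(list(time_ms = (seq_len(nf - 1) - 0.5) * dt_ms,
                 speed_um_s = speed, frame_rate = movie$frame_rate),
            class = "velocity_trace")
}

#' Contraction and relaxation velocities from a speed trace
#'
#' Detects peaks in the pixel-speed trace (same detector as the calcium
#' module), pairs consecutive peaks into beats by temporal adjacency, and
#' labels the first peak of each pair as the contraction stroke and the
#' second as relaxation — in a beating monolayer the recoil follows the
#' contraction. An unpaired trailing peak is dropped with a warning.
#'
#' @param trace a `velocity_trace`.
#' @param min_prominence minimum peak prominence in um/s; `NULL`
#'   (default) uses a quarter of the trace maximum.
#' @param min_separation_ms minimum peak spacing (default 150 ms).
#' @return a `contractility_metrics` list: `mean_contraction_velocity_um_s`,
#'   `mean_relaxation_velocity_um_s`, `n_beats`, and `peak_pairs` — a
#'   data.frame with per-beat contraction/relaxation peak times and
#'   speeds.
#' @export
contraction_relaxation_metrics <- function(trace, min_prominence = NULL,
                                           min_separation_ms = 150) {
  stopifnot(inherits(trace, "velocity_trace"))
  y <- trace$speed_um_s
  if (is.null(min_prominence)) min_prominence <- max(y) / 4
  dt_ms <- 1000 / trace$frame_rate
  idx <- find_peaks_1d(y, min_prominence,
                       max(2, round(min_separation_ms / dt_ms)))
  if (length(idx) < 2)
    stop("fewer than 2 velocity peaks detected: no complete beat")
  if (length(idx) %% 2 == 1) {
    warning("odd trailing velocity peak dropped")
    idx <- idx[-length(idx)]
  }
  n_beats <- length(idx) / 2
  ci <- idx[seq(1, length(idx), by = 2)]
  ri <- idx[seq(2, length(idx), by = 2)]
  pairs <- data.frame(beat = seq_len(n_beats),
                      contraction_time_ms = trace$time_ms[ci],
                      contraction_um_s = y[ci],
                      relaxation_time_ms = trace$time_ms[ri],
                      relaxation_um_s = y[ri])
  structure(list(mean_contraction_velocity_um_s = mean(y[ci]),
                 mean_relaxation_velocity_um_s = mean(y[ri]),
                 n_beats = n_beats, peak_pairs = pairs),
            class = "contractility_metrics")
}

#' @export
print.contractility_metrics <- function(x, ...) {
  cat(sprintf(paste0("<contractility_metrics> contraction %.3g um/s,",
                     " relaxation %.3g um/s over %d beats\n"),
              x$mean_contraction_velocity_um_s,
              x$mean_relaxation_velocity_um_s, x$n_beats))
  invisible(x)
}

#' Write contractility outputs
#'
#' @param trace a `velocity_trace`.
#' @param metrics a `contractility_metrics`.
#' @param csv_path,json_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_contractility_outputs <- function(trace, metrics, csv_path, json_path) {
  utils::write.csv(data.frame(time_ms = trace$time_ms,
                              speed_um_s = trace$speed_um_s),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(mean_contraction_velocity_um_s = metrics$mean_contraction_velocity_um_s,
         mean_relaxation_velocity_um_s = metrics$mean_relaxation_velocity_um_s,
         n_beats = metrics$n_beats),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
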