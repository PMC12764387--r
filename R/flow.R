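#' Preprocess a calcium movie for optical flow
#'
#' Standard wave-imaging preprocessing: a 3x3 spatial median filter per
#' frame (removing isolated hot pixels) followed by a zero-phase
#' low-pass temporal filter per pixel. The temporal filter is a
#' second-order Butterworth run forwards and backwards
#' ([signal::filtfilt()]), so peak-arrival times are not shifted.
#'
#' @param movie a `cw_movie` with at least 10 frames.
#' @param spatial_median_px median window size; currently 3 (a 3x3
#'   window) is supported.
#' @param temporal_cutoff_hz low-pass cutoff, default 1 Hz; must be below
#'   the Nyquist frequency `frame_rate / 2`.
#' @return the filtered `cw_movie`.
#' @export
preprocess_movie <- function(movie, spatial_median_px = 3,
                             temporal_cutoff_hz = 1.0) {
  stopifnot(inherits(movie, "cw_movie"))
  nf <- n_frames(movie)
  if (nf < 10) stop("preprocessing needs at least 10 frames")
  if (spatial_median_px != 3)
    stop("only a 3x3 spatial median window is supported")
  if (temporal_cutoff_hz >= movie$frame_rate / 2)
    stop("temporal_cutoff_hz must be below the Nyquist frequency")
  out <- movie$frames
  for (t in seq_len(nf)) out[, , t] <- median_filter3(out[, , t])
  d <- dim(out)
  flat <- t(matrix(out, nrow = d[1] * d[2], ncol = d[3]))  # time x pixels
  flat <- butter2_lowpass_zp(flat, temporal_cutoff_hz, movie$frame_rate)
  out <- array(t(flat), dim = d)
  out[out < 0] <- 0
  cw_movie(out, movie$frame_rate, movie$pixel_size)
}

# exact 3x3 median filter (replicate edges), computed for all pixels at
# once with Paeth's 19-comparison median-of-9 sorting network over the
# nine shifted copies of the image
median_filter3 <- function(m) {
  e <- list(shift_mat(m, -1, -1), shift_mat(m, -1, 0), shift_mat(m, -1, 1),
            shift_mat(m, 0, -1), m, shift_mat(m, 0, 1),
            shift_mat(m, 1, -1), shift_mat(m, 1, 0), shift_mat(m, 1, 1))
  op <- function(i, j) {
    lo <- pmin(e[[i]], e[[j]]); hi <- pmax(e[[i]], e[[j]])
    e[[i]] <<- lo; e[[j]] <<- hi
  }
  op(2, 3); op(5, 6); op(8, 9); op(1, 2); op(4, 5); op(7, 8); op(2, 3)
  op(5, 6); op(8, 9); op(1, 4); op(6, 9); op(5, 8); op(4, 7); op(2, 5)
  op(3, 6); op(5, 8); op(5, 3); op(7, 5); op(5, 3)
  e[[5]]
}

# zero-phase second-order Butterworth low-pass applied along the rows
# (time) of a time-by-series matrix. The forward-backward cascade of a
# Butterworth has the squared magnitude response |H(f)|^2 =
# 1 / (1 + (f/fc)^4) and zero phase; it is applied spectrally on a
# mirror-extended series, which avoids the end transients of recursive
# filtering while keeping the identical steady-state response.
butter2_lowpass_zp <- function(x, cutoff_hz, fs) {
  n <- nrow(x)
  ext <- rbind(x, x[n:1, , drop = FALSE])   # even extension: continuous ends
  nn <- 2L * n
  f <- (seq_len(nn) - 1) / nn * fs
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  H <- 1 / (1 + (f / cutoff_hz)^4)
  y <- Re(stats::mvfft(stats::mvfft(ext) * H, inverse = TRUE)) / nn
  y[seq_len(n), , drop = FALSE]
}

#' Horn-Schunck optical flow between two frames
#'
#' Estimates the dense velocity field `(u, v)` minimizing the classical
#' global functional: squared brightness-constancy residual
#' `(Ex u + Ey v + Et)^2` plus `alpha^2` times the squared flow gradient.
#' Spatiotemporal derivatives are the standard averages over the 2x2x2
#' frame cube and the solution is obtained by Jacobi-style iteration with
#' the 8-neighbour weighted average.
#'
#' Components are in pixels/frame: `u` along columns (+x) and `v` along
#' rows (+y, downwards); the vector points in the direction of apparent
#' motion from `frame_a` to `frame_b`.
#'
#' @param frame_a,frame_b numeric matrices of identical shape, finite.
#' @param alpha smoothness weight (default 1).
#' @param n_iter maximum iterations (default 200).
#' @param tol stop when the mean absolute update of `(u, v)` falls below
#'   this value (default 1e-4).
#' @return a `flow_field`: list with matrices `u`, `v` and the iteration
#'   count `iterations`.
#' @export
horn_schunck <- function(frame_a, frame_b, alpha = 1, n_iter = 200,
                         tol = 1e-4) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b),
            all(dim(frame_a) == dim(frame_b)), alpha > 0)
  if (!all(is.finite(frame_a)) || !all(is.finite(frame_b)))
    stop("frames must be finite")
  a <- frame_a; b <- frame_b
  # derivative estimates averaged over the 2x2x2 cube (forward differences
  # evaluated at the cube centre)
  sx <- function(m) shift_mat(m, 0, -1)   # m[i, j+1]
  sy <- function(m) shift_mat(m, -1, 0)   # m[i+1, j]
  sxy <- function(m) shift_mat(m, -1, -1) # m[i+1, j+1]
  Ex <- (sx(a) - a + sxy(a) - sy(a) + sx(b) - b + sxy(b) - sy(b)) / 4
  Ey <- (sy(a) - a + sxy(a) - sx(a) + sy(b) - b + sxy(b) - sx(b)) / 4
  Et <- (b - a + sx(b) - sx(a) + sy(b) - sy(a) + sxy(b) - sxy(a)) / 4
  res <- hs_iterate(Ex, Ey, Et, alpha, as.integer(n_iter), tol)
  structure(list(u = res$u, v = res$v, iterations = res$iterations),
            class = "flow_field")
}

#' Optical flow over a whole movie
#'
#' Runs [horn_schunck()] on every consecutive frame pair and builds the
#' active-tissue mask: pixels whose temporal ΔF/F0 range is below
#' `mask_threshold` times the median per-pixel range are excluded from
#' downstream statistics.
#'
#' @param movie a `cw_movie`, normally already passed through
#'   [preprocess_movie()].
#' @param alpha,n_iter,tol Horn-Schunck settings (see [horn_schunck()]).
#' @param mask_threshold signal-mask threshold as a fraction of the
#'   median per-pixel ΔF/F0 range (default 0.2).
#' @return a `flow_sequence`: list with `fields` (one `flow_field` per
#'   frame pair), logical `mask`, `pixel_size`, `frame_rate`.
#' @export
compute_flow_sequence <- function(movie, alpha = 1, n_iter = 200,
                                  tol = 1e-4, mask_threshold = 0.2) {
  stopifnot(inherits(movie, "cw_movie"))
  nf <- n_frames(movie)
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, nrow = d[1] * d[2], ncol = nf)
  f0 <- apply(flat, 1, stats::quantile, probs = 0.10, names = FALSE)
  f0[f0 <= 0] <- NA
  rng <- (apply(flat, 1, max) - apply(flat, 1, min)) / f0
  rng[is.na(rng)] <- 0
  med <- stats::median(rng)
  mask <- matrix(if (med > 0) rng >= mask_threshold * med else TRUE,
                 d[1], d[2])
  fields <- lapply(seq_len(nf - 1), function(t)
    horn_schunck(movie$frames[, , t], movie$frames[, , t + 1],
                 alpha = alpha, n_iter = n_iter, tol = tol))
  structure(list(fields = fields, mask = mask,
                 pixel_size = movie$pixel_size,
                 frame_rate = movie$frame_rate),
            class = "flow_sequence")
}

# pooled masked vectors of a flow sequence: matrix with columns u, v
pooled_vectors <- function(flows) {
  sel <- which(flows$mask)
  do.call(rbind, lapply(flows$fields, function(f)
    cbind(u = f$u[sel], v = f$v[sel])))
}

#' Summary statistics of a flow sequence
#'
#' Pools the masked vectors of all frame pairs and reports the mean
#' vector magnitude in um/s plus circular statistics of the vector phase
#' `theta = atan2(v, u)`: the circular mean direction and the circular
#' variance `1 - |mean(exp(i theta))|` (0 for perfectly aligned flow, 1
#' for uniformly dispersed directions). Phase statistics are unweighted
#' but exclude vectors below a magnitude floor, so near-zero noise
#' vectors between wavefront transits do not dilute directionality.
#'
#' @param flows a `flow_sequence`.
#' @param magnitude_floor phase-statistics floor in pixels/frame;
#'   `NULL` (default) uses the 10th percentile of the pooled masked
#'   magnitudes.
#' @return a `flow_summary`: list with `mean_magnitude_um_s`,
#'   `circular_variance`, `circular_mean_rad`, `n_vectors` (vectors
#'   entering the phase statistics), `n_pooled`, and the floor used.
#' @export
flow_summary <- function(flows, magnitude_floor = NULL) {
  stopifnot(inherits(flows, "flow_sequence"))
  vec <- pooled_vectors(flows)
  if (!nrow(vec)) stop("no masked vectors available")
  mag <- sqrt(vec[, 1]^2 + vec[, 2]^2)
  mean_mag <- mean(mag) * flows$pixel_size * flows$frame_rate
  if (is.null(magnitude_floor))
    magnitude_floor <- stats::quantile(mag, 0.10, names = FALSE)
  keep <- mag > magnitude_floor
  if (!any(keep)) stop("no vectors above the magnitude floor")
  th <- atan2(vec[keep, 2], vec[keep, 1])
  C <- mean(cos(th)); S <- mean(sin(th))
  structure(list(mean_magnitude_um_s = mean_mag,
                 circular_variance = 1 - sqrt(C^2 + S^2),
                 circular_mean_rad = atan2(S, C),
                 n_vectors = sum(keep), n_pooled = nrow(vec),
                 magnitude_floor = magnitude_floor),
            class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf(paste0("<flow_summary> mean |v| = %.3g um/s, circular",
                     " variance = %.3g (mean dir %.1f deg, n = %d)\n"),
              x$mean_magnitude_um_s, x$circular_variance,
              x$circular_mean_rad * 180 / pi, x$n_vectors))
  invisible(x)
}

#' Rose histogram of flow directions
#'
#' Bins the phases of the pooled masked vectors (above the magnitude
#' floor) into equal-width sectors over `[-pi, pi)`, the data behind a
#' polar rose plot of wave directionality.
#'
#' @param flows a `flow_sequence`.
#' @param n_bins number of sectors, >= 4 (default 16).
#' @param magnitude_floor as in [flow_summary()].
#' @return data.frame with `bin_start_rad`, `bin_end_rad`, `count`;
#'   counts sum to the number of vectors above the floor.
#' @export
rose_histogram <- function(flows, n_bins = 16, magnitude_floor = NULL) {
  stopifnot(inherits(flows, "flow_sequence"), n_bins >= 4)
  vec <- pooled_vectors(flows)
  mag <- sqrt(vec[, 1]^2 + vec[, 2]^2)
  if (is.null(magnitude_floor))
    magnitude_floor <- stats::quantile(mag, 0.10, names = FALSE)
  th <- atan2(vec[mag > magnitude_floor, 2], vec[mag > magnitude_floor, 1])
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- pmin(findInterval(th, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_start_rad = edges[-(n_bins + 1)], bin_end_rad = edges[-1],
             count = counts)
}
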