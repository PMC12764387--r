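#' Calcium transient kernel
#'
#' Canonical single-transient shape used by all generators: a linear rise
#' from baseline to peak over `rise_ms`, followed by exponential decay
#' with constant `tau_ms`. The shape has a closed-form full width at half
#' maximum, `rise_ms / 2 + tau_ms * log(2)`, which makes it a convenient
#' ground truth for kinetics estimators: the half-maximum is crossed at
#' `rise_ms / 2` on the way up and at `rise_ms + tau_ms * log(2)` on the
#' way down.
#'
#' Defaults (500 ms rise, 360 ms decay, unit ΔF/F0 amplitude) give
#' transients with FWHM ~500 ms and τ = 360 ms, matching the kinetics
#' reported for day-10 hiPSC-CM GCaMP recordings, and decay well within
#' a 2 s beat period (`rise_ms + 3 * tau_ms < 2000`).
#'
#' @param rise_ms linear rise time to peak, ms, > 0.
#' @param tau_ms exponential decay constant, ms, > 0.
#' @param amplitude peak height in ΔF/F0 units, > 0.
#' @return object of class `transient_kernel`.
#' @export
transient_kernel <- function(rise_ms = 500, tau_ms = 360, amplitude = 1) {
  stopifnot(rise_ms > 0, tau_ms > 0, amplitude > 0)
  structure(list(rise_ms = rise_ms, tau_ms = tau_ms, amplitude = amplitude),
            class = "transient_kernel")
}

#' Evaluate a transient kernel
#'
#' @param kernel a `transient_kernel`.
#' @param t_ms time since transient onset, ms (vectorized; values < 0
#'   evaluate to 0).
#' @return intensity in the kernel's ΔF/F0 units.
#' @export
kernel_eval <- function(kernel, t_ms) {
  stopifnot(inherits(kernel, "transient_kernel"))
  out <- numeric(length(t_ms))
  rising <- t_ms >= 0 & t_ms <= kernel$rise_ms
  falling <- t_ms > kernel$rise_ms
  out[rising] <- kernel$amplitude * t_ms[rising] / kernel$rise_ms
  out[falling] <- kernel$amplitude *
    exp(-(t_ms[falling] - kernel$rise_ms) / kernel$tau_ms)
  dim(out) <- dim(t_ms)
  out
}

#' Analytic FWHM of a transient kernel
#'
#' @param kernel a `transient_kernel`.
#' @return full width at half maximum in ms:
#'   `rise_ms / 2 + tau_ms * log(2)`.
#' @export
kernel_fwhm <- function(kernel) {
  stopifnot(inherits(kernel, "transient_kernel"))
  kernel$rise_ms / 2 + kernel$tau_ms * log(2)
}

#' Generate a synthetic ROI trace set
#'
#' Builds per-ROI fluorescence beat trains with known timing: each ROI
#' fires once per period, with an independent Gaussian timing offset per
#' ROI and beat (`jitter_sd_ms`) and white Gaussian intensity noise. The
#' injected offsets are recorded in the ground truth, so synchronicity
#' statistics computed downstream can be checked against the exact
#' injected sample.
#'
#' Raw intensities are `baseline * (1 + sum of kernels)`, so the kernel
#' amplitude is the true ΔF/F0 peak height and `noise_sd` is expressed in
#' ΔF/F0 units (noise standard deviation = `baseline * noise_sd`);
#' `noise_sd = amplitude / 10` corresponds to SNR 10.
#'
#' @param n_rois number of ROIs.
#' @param n_beats number of beats in the train.
#' @param period_ms beat period, ms; must exceed `rise_ms + tau_ms` (and
#'   should exceed `rise_ms + 3 * tau_ms` so that transients decay before
#'   the next beat).
#' @param kernel a `transient_kernel`.
#' @param jitter_sd_ms SD of the per-ROI, per-beat peak-time offsets, ms.
#' @param noise_sd white-noise SD in ΔF/F0 units.
#' @param frame_rate sampling rate, frames/s (default 20).
#' @param baseline baseline fluorescence F0, intensity units.
#' @param seed RNG seed; identical arguments and seed give bit-identical
#'   output.
#' @return list with `traces` (a `trace_set` of *raw* intensities: fields
#'   `time_ms`, `raw` frame-by-ROI matrix, `roi_ids`, `frame_rate`) and
#'   `truth` (list: nominal and jittered `peak_times_ms`
#'   (beat-by-ROI matrices), `offsets_ms`, kernel, period, noise, seed).
#' @export
generate_trace_set <- function(n_rois = 16, n_beats = 8, period_ms = 2000,
                               kernel = transient_kernel(),
                               jitter_sd_ms = 0, noise_sd = 0,
                               frame_rate = 20, baseline = 100, seed = 1) {
  stopifnot(n_rois >= 1, n_beats >= 1, period_ms > 0, jitter_sd_ms >= 0,
            noise_sd >= 0, baseline > 0)
  if (period_ms <= kernel$rise_ms + kernel$tau_ms)
    stop("period_ms too short for the kernel (needs > rise_ms + tau_ms)")
  if (!is.null(seed)) set.seed(seed)
  dt_ms <- 1000 / frame_rate
  total_ms <- n_beats * period_ms + period_ms / 2
  nf <- ceiling(total_ms / dt_ms)
  time_ms <- (seq_len(nf) - 1) * dt_ms
  onsets <- (seq_len(n_beats) - 1) * period_ms + period_ms / 4
  offsets <- matrix(if (jitter_sd_ms > 0)
                      stats::rnorm(n_beats * n_rois, 0, jitter_sd_ms)
                    else 0,
                    nrow = n_beats, ncol = n_rois)
  raw <- matrix(0, nrow = nf, ncol = n_rois)
  for (r in seq_len(n_rois)) {
    s <- numeric(nf)
    for (b in seq_len(n_beats))
      s <- s + kernel_eval(kernel, time_ms - onsets[b] - offsets[b, r])
    raw[, r] <- baseline * (1 + s)
  }
  if (noise_sd > 0)
    raw <- raw + baseline * noise_sd * stats::rnorm(length(raw))
  raw[raw < 0] <- 0
  roi_ids <- sprintf("roi_%02d", seq_len(n_rois))
  colnames(raw) <- roi_ids
  colnames(offsets) <- roi_ids
  peak_times <- outer(onsets + kernel$rise_ms, rep(1, n_rois)) + offsets
  colnames(peak_times) <- roi_ids
  traces <- structure(list(time_ms = time_ms, raw = raw, roi_ids = roi_ids,
                           frame_rate = frame_rate),
                      class = "trace_set")
  truth <- list(pattern = "trace_set", period_ms = period_ms,
                kernel = kernel, jitter_sd_ms = jitter_sd_ms,
                noise_sd = noise_sd, baseline = baseline,
                onsets_ms = onsets, offsets_ms = offsets,
                peak_times_ms = peak_times, seed = seed)
  list(traces = traces, truth = truth)
}

#' Generate a synthetic calcium-wave movie
#'
#' Emulates a GCaMP recording of a beating monolayer. Every pixel fires
#' periodically with the transient kernel; the activation delay field sets
#' the propagation pattern:
#' \describe{
#'   \item{synchronous}{zero delay everywhere — the whole field peaks on
#'     the same frame.}
#'   \item{plane_wave}{delay proportional to the projection of the pixel
#'     position onto `direction`, i.e. a planar wavefront travelling at
#'     `speed` um/s along `direction` (radians, measured from the +x/
#'     column axis towards the +y/row axis).}
#'   \item{source}{delay proportional to radial distance from a centre
#'     point — a wave diverging outwards at `speed`.}
#'   \item{sink}{time-reversed radial ordering — the periphery fires first
#'     and the wave converges on the centre.}
#' }
#' Intensities are `baseline * (1 + kernel((t - delay) mod period))`,
#' blurred with a Gaussian optical PSF of `psf_sigma_px` pixels, plus
#' Gaussian noise of SD `baseline * noise_sd`, floored at zero. The PSF
#' emulates diffraction plus pixel integration; without it a slow wave's
#' rising front can be narrower than one pixel and the rendered scene
#' would be spatially aliased in a way no real microscope produces.
#'
#' @param h,w frame size in pixels.
#' @param pixel_size um per pixel.
#' @param frame_rate frames/s.
#' @param nframes number of frames (default 120 at 20 fps: a 6 s clip).
#' @param pattern `"synchronous"`, `"plane_wave"`, `"source"` or `"sink"`.
#' @param speed wave speed, um/s; required > 0 for propagating patterns.
#' @param direction plane-wave direction, radians.
#' @param period_ms beat period, ms (default 2000, i.e. 0.5 Hz beating).
#' @param kernel a `transient_kernel`.
#' @param noise_sd imaging noise SD in ΔF/F0 units.
#' @param baseline baseline fluorescence F0, intensity units.
#' @param psf_sigma_px SD of the Gaussian optical PSF in pixels
#'   (default 1; 0 disables blurring).
#' @param center source/sink centre as `c(row, col)`; defaults to the
#'   image centre.
#' @param seed RNG seed.
#' @return list with `movie` (a `cw_movie`) and `truth` (pattern
#'   geometry, per-pixel activation `delay_ms` and first-beat
#'   `peak_times_ms` matrices, kernel, noise, seed).
#' @export
generate_wave_movie <- function(h = 128, w = 128, pixel_size = 2,
                                frame_rate = 20, nframes = 120,
                                pattern = c("synchronous", "plane_wave",
                                            "source", "sink"),
                                speed = 10, direction = 0, period_ms = 2000,
                                kernel = transient_kernel(), noise_sd = 0.02,
                                baseline = 100, psf_sigma_px = 1,
                                center = NULL, seed = 1) {
  pattern <- match.arg(pattern)
  stopifnot(h >= 4, w >= 4, nframes >= 2, period_ms > 0, noise_sd >= 0)
  if (pattern != "synchronous" && speed <= 0)
    stop("speed must be > 0 for propagating patterns")
  if (nframes / frame_rate * 1000 < period_ms)
    stop("movie too short to contain one full beat period")
  if (!is.null(seed)) set.seed(seed)
  xs <- matrix((seq_len(w) - 1) * pixel_size, nrow = h, ncol = w, byrow = TRUE)
  ys <- matrix((seq_len(h) - 1) * pixel_size, nrow = h, ncol = w)
  delay_ms <- switch(pattern,
    synchronous = matrix(0, h, w),
    plane_wave = {
      proj <- xs * cos(direction) + ys * sin(direction)
      (proj - min(proj)) / speed * 1000
    },
    source = ,
    sink = {
      if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
      cx <- (center[2] - 1) * pixel_size
      cy <- (center[1] - 1) * pixel_size
      r <- sqrt((xs - cx)^2 + (ys - cy)^2)
      d <- r / speed * 1000
      if (pattern == "sink") max(d) - d else d
    })
  dt_ms <- 1000 / frame_rate
  frames <- array(0, dim = c(h, w, nframes))
  for (t in seq_len(nframes)) {
    phase <- ((t - 1) * dt_ms - delay_ms) %% period_ms
    fr <- baseline * (1 + kernel_eval(kernel, phase))
    if (psf_sigma_px > 0) fr <- gaussian_blur(fr, psf_sigma_px)
    frames[, , t] <- fr
  }
  if (noise_sd > 0)
    frames <- frames + baseline * noise_sd * stats::rnorm(length(frames))
  frames[frames < 0] <- 0
  movie <- cw_movie(frames, frame_rate, pixel_size)
  truth <- list(pattern = pattern, speed = speed, direction = direction,
                period_ms = period_ms, kernel = kernel, noise_sd = noise_sd,
                baseline = baseline, psf_sigma_px = psf_sigma_px,
                center = center, delay_ms = delay_ms,
                peak_times_ms = delay_ms + kernel$rise_ms, seed = seed)
  list(movie = movie, truth = truth)
}

#' Generate a synthetic beating-motion movie
#'
#' Emulates a phase-contrast recording of a contracting monolayer: a
#' static random texture is warped each frame by a radial displacement
#' field towards the image centre. The radial strain follows a smooth
#' periodic pulse — an inward (contraction) stroke taking
#' `contraction_fraction` of the beat, then an outward (relaxation)
#' stroke over the remainder — so each beat produces exactly two strokes
#' of pixel motion. With the same peak displacement covered in less time,
#' smaller `contraction_fraction` means faster contraction than
#' relaxation.
#'
#' @param h,w frame size, pixels.
#' @param pixel_size um per pixel.
#' @param frame_rate frames/s.
#' @param nframes number of frames.
#' @param beat_period_ms beat period, ms (default 1000, i.e. 1 Hz).
#' @param peak_displacement_px maximum feature displacement (at radius
#'   `min(h, w) / 2` from the centre), pixels, >= 0 and at most half the
#'   image size.
#' @param contraction_fraction fraction of the beat occupied by the
#'   contraction stroke, in (0, 1).
#' @param noise_sd per-frame Gaussian intensity noise SD (texture
#'   intensities span roughly [0.2, 1]).
#' @param texture_seed seed for the static texture (defaults to
#'   `seed + 1`, so the texture is reproducible but distinct from the
#'   noise stream).
#' @param seed RNG seed.
#' @return list with `movie` (a `cw_movie`) and `truth`, whose
#'   `speed_um_s` is the exact mean pixel speed between consecutive
#'   frames (length `nframes - 1`) and `contracting` flags frames pairs
#'   in the inward stroke.
#' @export
generate_motion_movie <- function(h = 64, w = 64, pixel_size = 2,
                                  frame_rate = 20, nframes = 100,
                                  beat_period_ms = 1000,
                                  peak_displacement_px = 3,
                                  contraction_fraction = 0.5,
                                  noise_sd = 0, texture_seed = NULL,
                                  seed = 1) {
  stopifnot(h >= 8, w >= 8, nframes >= 2, beat_period_ms > 0,
            peak_displacement_px >= 0, noise_sd >= 0)
  if (contraction_fraction <= 0 || contraction_fraction >= 1)
    stop("contraction_fraction must lie in (0, 1)")
  if (peak_displacement_px > min(h, w) / 2)
    stop("peak_displacement_px exceeds the image half-size")
  if (is.null(texture_seed)) texture_seed <- seed + 1L
  set.seed(texture_seed)
  tex <- matrix(stats::runif(h * w, 0.2, 1), h, w)
  for (i in 1:3) tex <- box_blur3(tex)
  if (!is.null(seed)) set.seed(seed)
  R <- min(h, w) / 2
  eps_max <- peak_displacement_px / R
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  t_ms <- (seq_len(nframes) - 1) * 1000 / frame_rate
  eps <- eps_max * stroke_profile((t_ms %% beat_period_ms) / beat_period_ms,
                                  contraction_fraction)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  frames <- array(0, dim = c(h, w, nframes))
  for (t in seq_len(nframes)) {
    # pixel p shows the texture point radially outward by factor (1 + eps):
    # features move towards the centre as eps grows
    qr <- cr + (rows - cr) * (1 + eps[t])
    qc <- cc + (cols - cc) * (1 + eps[t])
    frames[, , t] <- bilinear_sample(tex, qr, qc)
  }
  if (noise_sd > 0)
    frames <- frames + noise_sd * stats::rnorm(length(frames))
  frames[frames < 0] <- 0
  movie <- cw_movie(frames, frame_rate, pixel_size)
  # exact apparent speed: texture point at radius rho sits at rho/(1+eps),
  # so between frames it moves rho * |1/(1+e1) - 1/(1+e2)| pixels
  rho <- sqrt((rows - cr)^2 + (cols - cc)^2)
  mean_rho <- mean(rho)
  step <- abs(1 / (1 + eps[-1]) - 1 / (1 + eps[-nframes]))
  speed_um_s <- mean_rho * step * frame_rate * pixel_size
  contracting <- diff(eps) > 0
  truth <- list(pattern = "motion", beat_period_ms = beat_period_ms,
                peak_displacement_px = peak_displacement_px,
                contraction_fraction = contraction_fraction,
                eps = eps, speed_um_s = speed_um_s,
                contracting = contracting, noise_sd = noise_sd,
                texture_seed = texture_seed, seed = seed)
  list(movie = movie, truth = truth)
}

# periodic radial-strain profile on beat phase in [0, 1): smooth rise to 1
# over [0, f], smooth return to 0 over [f, 1]
stroke_profile <- function(phase, f) {
  ifelse(phase <= f,
         sin(pi * phase / (2 * f))^2,
         sin(pi * (1 - phase) / (2 * (1 - f)))^2)
}

# separable Gaussian blur (replicate edges), kernel truncated at 3 sigma
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  out <- 0 * m
  for (k in (-r):r) out <- out + g[k + r + 1] * shift_mat(m, 0, k)
  res <- 0 * m
  for (k in (-r):r) res <- res + g[k + r + 1] * shift_mat(out, k, 0)
  res
}

# 3x3 box blur with replicated edges
box_blur3 <- function(m) {
  (shift_mat(m, -1, -1) + shift_mat(m, -1, 0) + shift_mat(m, -1, 1) +
   shift_mat(m, 0, -1) + m + shift_mat(m, 0, 1) +
   shift_mat(m, 1, -1) + shift_mat(m, 1, 0) + shift_mat(m, 1, 1)) / 9
}

# shift a matrix by (dr, dc) with replicate padding
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# vectorized bilinear interpolation with replicate-edge clamping;
# rr, cc are matrices of (possibly fractional) row/col coordinates
bilinear_sample <- function(tex, rr, cc) {
  h <- nrow(tex); w <- ncol(tex)
  rr <- pmin(pmax(rr, 1), h)
  cc <- pmin(pmax(cc, 1), w)
  r0 <- pmin(floor(rr), h - 1); c0 <- pmin(floor(cc), w - 1)
  fr <- rr - r0; fc <- cc - c0
  i00 <- tex[cbind(c(r0), c(c0))]
  i01 <- tex[cbind(c(r0), c(c0 + 1))]
  i10 <- tex[cbind(c(r0 + 1), c(c0))]
  i11 <- tex[cbind(c(r0 + 1), c(c0 + 1))]
  out <- i00 * (1 - c(fr)) * (1 - c(fc)) + i01 * (1 - c(fr)) * c(fc) +
    i10 * c(fr) * (1 - c(fc)) + i11 * c(fr) * c(fc)
  matrix(out, nrow(rr), ncol(rr))
}

#' Trace set CSV I/O
#'
#' Writes/reads a trace set as CSV with a `time_ms` column followed by one
#' column per ROI (raw intensities).
#'
#' @param traces a `trace_set`.
#' @param path CSV path.
#' @return `read_trace_csv` returns a `trace_set`; the writer returns
#'   `path` invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  df <- data.frame(time_ms = traces$time_ms, traces$raw, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("time_ms" %in% names(df))
  time_ms <- df$time_ms
  raw <- as.matrix(df[setdiff(names(df), "time_ms")])
  dt <- stats::median(diff(time_ms))
  structure(list(time_ms = time_ms, raw = raw, roi_ids = colnames(raw),
                 frame_rate = 1000 / dt),
            class = "trace_set")
}
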