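#' Stimulation pulse specification
#'
#' Describes one pulse train of the stimulation device: pulse shape,
#' amplitude, per-phase duration and repetition frequency. "Phase duration"
#' is the width of a single polarity phase, so a biphasic pulse occupies
#' `2 * phase_duration_ms` of each period; set `total_duration = TRUE` to
#' interpret `phase_duration_ms` as the total biphasic width instead.
#'
#' @param shape one of `"biphasic"`, `"monophasic"`,
#'   `"alternating_monophasic"`. Biphasic pulses deliver a cathodic (+V)
#'   phase immediately followed by an equal anodic (-V) phase, giving zero
#'   net charge; alternating monophasic pulses are single-phase but flip
#'   polarity on successive periods.
#' @param voltage_V pulse amplitude in volts, > 0.
#' @param phase_duration_ms duration of one phase in milliseconds, > 0.
#' @param frequency_Hz pulse repetition frequency in hertz, > 0.
#' @param total_duration if `TRUE`, `phase_duration_ms` is the total pulse
#'   width (halved per phase for biphasic shapes).
#' @param device_limits if `TRUE`, enforce the physical device envelope:
#'   phase duration in [2, 1000] ms and frequency <= 50 Hz. Off by default
#'   so that synthetic studies may explore beyond the hardware range.
#' @return an object of class `pulse_spec`.
#' @examples
#' pulse_spec("biphasic", voltage_V = 4, phase_duration_ms = 4, frequency_Hz = 1)
#' @export
pulse_spec <- function(shape = c("biphasic", "monophasic", "alternating_monophasic"),
                       voltage_V, phase_duration_ms, frequency_Hz,
                       total_duration = FALSE, device_limits = FALSE) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(voltage_V), length(voltage_V) == 1L, is.finite(voltage_V),
            is.numeric(phase_duration_ms), length(phase_duration_ms) == 1L,
            is.numeric(frequency_Hz), length(frequency_Hz) == 1L)
  if (voltage_V <= 0) stop("voltage_V must be > 0")
  if (phase_duration_ms <= 0) stop("phase_duration_ms must be > 0")
  if (frequency_Hz <= 0) stop("frequency_Hz must be > 0")
  if (total_duration && shape == "biphasic") phase_duration_ms <- phase_duration_ms / 2
  width_ms <- pulse_width_ms(shape, phase_duration_ms)
  if (frequency_Hz * width_ms > 1000)
    stop("pulse of ", width_ms, " ms does not fit within the ",
         1000 / frequency_Hz, " ms period")
  if (device_limits) {
    if (phase_duration_ms < 2 || phase_duration_ms > 1000)
      stop("device supports phase durations of 2 ms to 1 s")
    if (frequency_Hz > 50) stop("device supports frequencies up to 50 Hz")
  }
  structure(list(shape = shape, voltage_V = voltage_V,
                 phase_duration_ms = phase_duration_ms,
                 frequency_Hz = frequency_Hz,
                 device_limits = device_limits),
            class = "pulse_spec")
}

# total occupied width of one pulse, ms
pulse_width_ms <- function(shape, phase_duration_ms) {
  if (shape == "biphasic") 2 * phase_duration_ms else phase_duration_ms
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf("<pulse_spec> %s, %.3g V, %.4g ms/phase, %.4g Hz\n",
              x$shape, x$voltage_V, x$phase_duration_ms, x$frequency_Hz))
  invisible(x)
}

#' Build a stimulation schedule
#'
#' A schedule holds the start and end pulse specification of a multi-day
#' regimen. Static schedules keep every parameter constant; ramped
#' schedules vary frequency or phase duration linearly in time between the
#' two endpoints (e.g. 1 to 2 Hz over 10 days, i.e. 0.1 Hz/day, or
#' 4 to 8 ms over 10 days, i.e. 0.4 ms/day).
#'
#' @param kind `"static"`, `"ramped_frequency"` or `"ramped_duration"`.
#' @param start,end `pulse_spec` endpoints. For `"static"` the endpoints
#'   must be identical; for a ramped schedule every field other than the
#'   ramped one must agree between `start` and `end`.
#' @param duration_days schedule length in days, > 0.
#' @return an object of class `regimen_schedule` with elements `kind`,
#'   `start`, `end`, `duration_days`, `ramped_fields`, and `rates` — a list
#'   with per-minute and per-day linear rates for frequency (Hz) and phase
#'   duration (ms).
#' @examples
#' s <- pulse_spec("biphasic", 4, 4, 1)
#' e <- pulse_spec("biphasic", 4, 4, 2)
#' sch <- build_schedule("ramped_frequency", s, e, duration_days = 10)
#' sch$rates$frequency_Hz_per_min   # 6.94e-5
#' @export
build_schedule <- function(kind = c("static", "ramped_frequency", "ramped_duration"),
                           start, end = start, duration_days) {
  kind <- match.arg(kind)
  stopifnot(inherits(start, "pulse_spec"), inherits(end, "pulse_spec"),
            is.numeric(duration_days), length(duration_days) == 1L)
  if (duration_days <= 0) stop("duration_days must be > 0")
  ramped_fields <- switch(kind,
    static = character(0),
    ramped_frequency = "frequency_Hz",
    ramped_duration = "phase_duration_ms")
  fixed <- setdiff(c("shape", "voltage_V", "phase_duration_ms", "frequency_Hz"),
                   ramped_fields)
  for (f in fixed) {
    if (!identical(start[[f]], end[[f]]))
      stop("field '", f, "' differs between endpoints but is not ramped")
  }
  total_min <- duration_days * 1440
  rates <- list(
    frequency_Hz_per_min = (end$frequency_Hz - start$frequency_Hz) / total_min,
    frequency_Hz_per_day = (end$frequency_Hz - start$frequency_Hz) / duration_days,
    phase_duration_ms_per_min =
      (end$phase_duration_ms - start$phase_duration_ms) / total_min,
    phase_duration_ms_per_day =
      (end$phase_duration_ms - start$phase_duration_ms) / duration_days)
  structure(list(kind = kind, start = start, end = end,
                 duration_days = duration_days,
                 ramped_fields = ramped_fields, rates = rates),
            class = "regimen_schedule")
}

#' @export
print.regimen_schedule <- function(x, ...) {
  cat(sprintf("<regimen_schedule> %s over %g days\n", x$kind, x$duration_days))
  cat("  start:"); print(x$start)
  cat("  end:  "); print(x$end)
  invisible(x)
}

#' Evaluate a schedule at a time point
#'
#' Linearly interpolates the ramped fields of a schedule, returning the
#' pulse specification in force `t_min` minutes after the regimen start.
#'
#' @param schedule a `regimen_schedule`.
#' @param t_min time since regimen start, in minutes; must lie within
#'   `[0, duration_days * 1440]`.
#' @return a `pulse_spec`.
#' @export
param_at <- function(schedule, t_min) {
  stopifnot(inherits(schedule, "regimen_schedule"),
            is.numeric(t_min), length(t_min) == 1L)
  total_min <- schedule$duration_days * 1440
  if (t_min < 0 || t_min > total_min)
    stop("t_min must lie in [0, ", total_min, "] minutes")
  frac <- t_min / total_min
  s <- schedule$start; e <- schedule$end
  pulse_spec(s$shape, s$voltage_V,
             s$phase_duration_ms + frac * (e$phase_duration_ms - s$phase_duration_ms),
             s$frequency_Hz + frac * (e$frequency_Hz - s$frequency_Hz),
             device_limits = s$device_limits)
}

#' Sample an ideal stimulation waveform
#'
#' Renders the voltage-versus-time trace an ideal generator would emit for
#' a pulse specification: the digital twin of an oscilloscope recording.
#'
#' @param spec a `pulse_spec`.
#' @param window_s length of the rendered trace in seconds; must cover at
#'   least one full period.
#' @param sample_rate_Hz sampling rate; must give at least 100 samples per
#'   phase so that threshold-crossing timing is meaningful.
#' @return a `sampled_waveform`: list with `time_s`, `voltage_V`,
#'   `sample_rate_Hz` and the nominal `spec`.
#' @examples
#' wf <- sample_waveform(pulse_spec("biphasic", 4, 4, 1), window_s = 2)
#' sum(wf$voltage_V) / wf$sample_rate_Hz   # ~0: charge balance
#' @export
sample_waveform <- function(spec, window_s, sample_rate_Hz = 1e5) {
  stopifnot(inherits(spec, "pulse_spec"))
  period_s <- 1 / spec$frequency_Hz
  if (window_s < period_s) stop("window_s must cover at least one period")
  phase_s <- spec$phase_duration_ms / 1000
  if (sample_rate_Hz < 100 / phase_s)
    stop("sample_rate_Hz must give at least 100 samples per phase")
  n <- floor(window_s * sample_rate_Hz)
  t <- (seq_len(n) - 1L) / sample_rate_Hz
  v <- numeric(n)
  V <- spec$voltage_V
  # pulses are laid out by sample index so that every phase holds exactly
  # the same number of samples: biphasic trains are then charge-balanced
  # to machine precision, not merely to one sample period
  npd <- round(phase_s * sample_rate_Hz)
  period_samp <- period_s * sample_rate_Hz
  for (k in 0:ceiling(n / period_samp)) {
    s0 <- round(k * period_samp)
    i1 <- (s0 + 1):(s0 + npd)
    i1 <- i1[i1 <= n]
    if (!length(i1)) next
    if (spec$shape == "biphasic") {
      v[i1] <- V
      i2 <- (s0 + npd + 1):(s0 + 2 * npd)
      v[i2[i2 <= n]] <- -V
    } else if (spec$shape == "monophasic") {
      v[i1] <- V
    } else { # alternating_monophasic
      v[i1] <- V * (if (k %% 2 == 0) 1 else -1)
    }
  }
  structure(list(time_s = t, voltage_V = v, sample_rate_Hz = sample_rate_Hz,
                 spec = spec),
            class = "sampled_waveform")
}

#' Measure pulse durations from a recorded waveform
#'
#' Recovers cathodic (positive-phase), anodic (negative-phase) and total
#' pulse durations from a sampled voltage trace by mid-amplitude threshold
#' crossing, the standard pulse-timing convention. Crossing times are
#' located by linear interpolation between bracketing samples and phase
#' durations are averaged over all pulses present in the trace.
#'
#' @param waveform a `sampled_waveform`, or a list with numeric `time_s`
#'   and `voltage_V` (e.g. read from an oscilloscope CSV).
#' @param amplitude_threshold_fraction crossing threshold as a fraction of
#'   the nominal amplitude (default 0.5, i.e. mid-amplitude). The nominal
#'   amplitude is `max(abs(voltage))`.
#' @return a list with `cathodic_ms`, `anodic_ms` and `total_ms`
#'   (`total = cathodic + anodic`; a purely monophasic trace has
#'   `anodic_ms = 0`).
#' @export
measure_pulse <- function(waveform, amplitude_threshold_fraction = 0.5) {
  v <- waveform$voltage_V
  t <- waveform$time_s
  stopifnot(length(v) == length(t), length(v) > 1L)
  if (amplitude_threshold_fraction <= 0 || amplitude_threshold_fraction >= 1)
    stop("amplitude_threshold_fraction must lie in (0, 1)")
  amp <- max(abs(v))
  if (amp == 0) stop("no pulse detected: waveform is identically zero")
  thr <- amplitude_threshold_fraction * amp
  cath <- run_durations_ms(t, v, thr)
  anod <- run_durations_ms(t, -v, thr)
  if (length(cath) == 0 && length(anod) == 0)
    stop("no pulse detected: no threshold crossings found")
  cathodic <- if (length(cath)) mean(cath) else 0
  anodic <- if (length(anod)) mean(anod) else 0
  list(cathodic_ms = cathodic, anodic_ms = anodic,
       total_ms = cathodic + anodic)
}

# durations (ms) of contiguous runs where x exceeds thr, with the run
# boundaries refined by linear interpolation of the threshold crossing
run_durations_ms <- function(t, x, thr) {
  above <- x > thr
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(t)
  vapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    t0 <- if (s > 1L) {
      # interpolate crossing between s-1 (below) and s (above)
      t[s - 1L] + (thr - x[s - 1L]) / (x[s] - x[s - 1L]) * (t[s] - t[s - 1L])
    } else t[s]
    t1 <- if (e < n) {
      t[e] + (thr - x[e]) / (x[e + 1L] - x[e]) * (t[e + 1L] - t[e])
    } else t[e]
    (t1 - t0) * 1000
  }, numeric(1))
}

#' Signal fidelity report
#'
#' Compares measured pulse durations with the programmed (expected) values
#' and reports the percent error for each quantity, as used to validate
#' the stimulation hardware against oscilloscope recordings.
#'
#' @param measured list with `cathodic_ms`, `anodic_ms`, `total_ms`
#'   (e.g. from [measure_pulse()]).
#' @param expected list with `cathodic_ms`, `anodic_ms`, `total_ms` of the
#'   programmed pulse. Expected durations of exactly zero (e.g. the anodic
#'   phase of a monophasic pulse) yield `NA` percent error rather than a
#'   division by zero, unless the measured value is also zero (0% error).
#' @return a `fidelity_report`: measured and expected durations plus
#'   `percent_error` (named vector over cathodic/anodic/total).
#' @export
fidelity_report <- function(measured, expected) {
  q <- c("cathodic_ms", "anodic_ms", "total_ms")
  m <- vapply(q, function(k) as.numeric(measured[[k]]), numeric(1))
  e <- vapply(q, function(k) as.numeric(expected[[k]]), numeric(1))
  if (any(e < 0)) stop("expected durations must be >= 0")
  pe <- ifelse(e == 0, ifelse(m == 0, 0, NA_real_), abs(m - e) / e * 100)
  names(pe) <- c("cathodic", "anodic", "total")
  structure(list(measured = m, expected = e, percent_error = pe),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>\n")
  df <- data.frame(measured_ms = x$measured, expected_ms = x$expected,
                   percent_error = x$percent_error,
                   row.names = names(x$percent_error))
  print(df)
  invisible(x)
}

#' Expected phase durations of a pulse specification
#'
#' Helper giving the programmed cathodic/anodic/total durations implied by
#' a `pulse_spec`, for use as the `expected` argument of
#' [fidelity_report()]. Monophasic pulses have zero anodic duration; for
#' alternating monophasic trains both polarities occur, one per period.
#'
#' @param spec a `pulse_spec`.
#' @return list with `cathodic_ms`, `anodic_ms`, `total_ms`.
#' @export
expected_durations <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  pd <- spec$phase_duration_ms
  switch(spec$shape,
    biphasic = list(cathodic_ms = pd, anodic_ms = pd, total_ms = 2 * pd),
    monophasic = list(cathodic_ms = pd, anodic_ms = 0, total_ms = pd),
    alternating_monophasic =
      list(cathodic_ms = pd, anodic_ms = pd, total_ms = 2 * pd))
}

#' Read a regimen configuration from JSON
#'
#' The configuration carries `shape`, `voltage_V`, `phase_duration_ms`,
#' `frequency_Hz` and optionally `ramp` with `field`
#' (`"frequency_Hz"`/`"phase_duration_ms"`), `end_value` and
#' `duration_days`. Without a `ramp` entry a static schedule over
#' `duration_days` (default 10) is built.
#'
#' @param path path to a JSON file.
#' @param duration_days schedule length for static configurations.
#' @return a `regimen_schedule`.
#' @export
read_regimen_config <- function(path, duration_days = 10) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("shape", "voltage_V", "phase_duration_ms", "frequency_Hz")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("regimen config missing fields: ",
                         paste(miss, collapse = ", "))
  start <- pulse_spec(cfg$shape, cfg$voltage_V, cfg$phase_duration_ms,
                      cfg$frequency_Hz)
  if (is.null(cfg$ramp))
    return(build_schedule("static", start, start, duration_days))
  ramp <- cfg$ramp
  if (!ramp$field %in% c("frequency_Hz", "phase_duration_ms"))
    stop("ramp$field must be 'frequency_Hz' or 'phase_duration_ms'")
  endv <- list(frequency_Hz = cfg$frequency_Hz,
               phase_duration_ms = cfg$phase_duration_ms)
  endv[[ramp$field]] <- ramp$end_value
  end <- pulse_spec(cfg$shape, cfg$voltage_V, endv$phase_duration_ms,
                    endv$frequency_Hz)
  kind <- if (ramp$field == "frequency_Hz") "ramped_frequency" else "ramped_duration"
  build_schedule(kind, start, end, ramp$duration_days)
}

#' Waveform CSV I/O
#'
#' Reads/writes sampled waveforms as two-column CSV (`time_s`,
#' `voltage_V`), the format produced by oscilloscope exports.
#'
#' @param waveform a `sampled_waveform`.
#' @param path CSV file path.
#' @return `read_waveform_csv` returns a `sampled_waveform` (sample rate
#'   inferred from the median time step); `write_waveform_csv` returns
#'   `path` invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(data.frame(time_s = waveform$time_s,
                              voltage_V = waveform$voltage_V),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "voltage_V") %in% names(df)))
  dt <- stats::median(diff(df$time_s))
  structure(list(time_s = df$time_s, voltage_V = df$voltage_V,
                 sample_rate_Hz = 1 / dt, spec = NULL),
            class = "sampled_waveform")
}
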