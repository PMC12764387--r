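#' Tabulate a stimulation schedule
#'
#' Samples a schedule along its span, giving the per-time-point frequency
#' and phase duration — the digital counterpart of the device's exported
#' stimulation logs. The first and last rows are exactly the schedule
#' endpoints.
#'
#' @param schedule a `regimen_schedule`.
#' @param step_minutes sampling step in minutes, > 0. A step larger than
#'   the schedule span yields the two endpoint rows with a warning.
#' @return `data.frame(t_min, frequency_Hz, phase_duration_ms)`.
#' @examples
#' s <- pulse_spec("biphasic", 4, 4, 1)
#' e <- pulse_spec("biphasic", 4, 4, 2)
#' regimen_log(build_schedule("ramped_frequency", s, e, 10), 1440)
#' @export
regimen_log <- function(schedule, step_minutes) {
  stopifnot(inherits(schedule, "regimen_schedule"), step_minutes > 0)
  total_min <- schedule$duration_days * 1440
  if (step_minutes > total_min)
    warning("step_minutes exceeds the schedule span; returning endpoints only")
  t <- seq(0, total_min, by = step_minutes)
  if (t[length(t)] < total_min) t <- c(t, total_min)
  specs <- lapply(t, function(ti) param_at(schedule, ti))
  data.frame(t_min = t,
             frequency_Hz = vapply(specs, `[[`, numeric(1), "frequency_Hz"),
             phase_duration_ms = vapply(specs, `[[`, numeric(1),
                                        "phase_duration_ms"))
}

#' Validate a run configuration
#'
#' Checks a pipeline configuration before any computation: a `seed`, a
#' nonempty `conditions` list, and for every condition a `name` plus at
#' least one input block (`movie`, `traces` or `motion`). Raises an
#' informative error on the first violation, so an invalid run produces
#' no partial output.
#'
#' @param config configuration list, or path to a JSON file.
#' @return the parsed configuration list, invisibly valid.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config$seed must be a number")
  conds <- config$conditions
  if (is.null(conds) || !length(conds)) stop("config$conditions is empty")
  nms <- vapply(conds, function(cd) {
    if (is.null(cd$name)) stop("every condition needs a name")
    if (is.null(cd$movie) && is.null(cd$traces) && is.null(cd$motion))
      stop("condition '", cd$name,
           "' has no input block (movie, traces or motion)")
    cd$name
  }, character(1))
  if (anyDuplicated(nms)) stop("condition names must be unique")
  config
}

kernel_from_config <- function(k) {
  if (is.null(k)) return(transient_kernel())
  transient_kernel(rise_ms = k$rise_ms %||% 500, tau_ms = k$tau_ms %||% 360,
                   amplitude = k$amplitude %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes every configured condition at desk scale: generates (or
#' loads) its inputs, runs the calcium-trace metrics (peaks, FWHM, tau,
#' TPA-MAD), the optical-flow summary for movie inputs and the
#' contractility metrics for motion inputs, writes all per-condition
#' artifacts into `out_dir`, and returns a one-row-per-condition report.
#' Identical configuration and seed give byte-identical outputs.
#'
#' Per-stage seeds are derived deterministically from the global seed as
#' `seed + 101 * condition_index + stage` (stage 1 = movie, 2 = traces,
#' 3 = motion), so any stage can be regenerated in isolation.
#'
#' Condition blocks:
#' \describe{
#'   \item{regimen}{optional; keys as in [read_regimen_config()]; a
#'     schedule log is written.}
#'   \item{movie}{arguments of [generate_wave_movie()]; or
#'     `{"tiff": path}` to load a recording.}
#'   \item{traces}{arguments of [generate_trace_set()]; or
#'     `{"csv": path}`.}
#'   \item{motion}{arguments of [generate_motion_movie()]; or
#'     `{"tiff": path}`.}
#' }
#'
#' @param config configuration list or JSON path; see
#'   [validate_run_config()].
#' @param out_dir output directory, created if needed.
#' @return a `run_report`: list with `metrics` (data.frame, one row per
#'   condition), `config_hash`, `seed`, and `out_dir`. The metrics table
#'   is also written to `report.csv` (with a commented provenance
#'   header) and `report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  an <- config$analysis %||% list()
  grid <- unlist(an$grid %||% c(4, 4))
  rows <- lapply(seq_along(config$conditions), function(ci) {
    cd <- config$conditions[[ci]]
    run_condition(cd, ci, config$seed, an, grid, out_dir, hash)
  })
  metrics <- do.call(rbind, rows)
  header <- c(paste0("# config_hash: ", hash),
              paste0("# seed: ", config$seed),
              paste0("# package: cardiowave ",
                     as.character(utils::packageVersion("cardiowave"))))
  report_csv <- file.path(out_dir, "report.csv")
  writeLines(header, report_csv)
  suppressWarnings(utils::write.table(metrics, report_csv, append = TRUE,
                                      sep = ",", row.names = FALSE,
                                      qmethod = "double"))
  jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                            metrics = metrics),
                       file.path(out_dir, "report.json"), digits = NA)
  structure(list(metrics = metrics, config_hash = hash, seed = config$seed,
                 out_dir = out_dir),
            class = "run_report")
}

run_condition <- function(cd, ci, seed, an, grid, out_dir, hash) {
  name <- cd$name
  hs_alpha <- an$hs_alpha %||% 1
  hs_iter <- an$hs_n_iter %||% 200
  hs_tol <- an$hs_tol %||% 1e-4
  prom <- an$min_prominence_dff %||% 0.2
  sep <- an$min_separation_ms %||% 250
  mask_thr <- an$mask_threshold %||% 0.2
  out <- list(condition = name, tpa_mad_ms = NA_real_,
              median_fwhm_ms = NA_real_, median_tau_ms = NA_real_,
              mean_magnitude_um_s = NA_real_, circular_variance = NA_real_,
              mean_contraction_velocity_um_s = NA_real_,
              mean_relaxation_velocity_um_s = NA_real_)
  if (!is.null(cd$regimen)) {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(cd$regimen, tmp, auto_unbox = TRUE, digits = NA)
    sch <- read_regimen_config(tmp)
    unlink(tmp)
    log <- regimen_log(sch, step_minutes = 1440)
    utils::write.csv(log, file.path(out_dir,
                                    paste0(name, "_regimen_log.csv")),
                     row.names = FALSE)
  }
  traces <- NULL
  if (!is.null(cd$movie)) {
    mv <- cd$movie
    movie <- if (!is.null(mv$tiff)) read_movie_tiff(mv$tiff)
    else generate_wave_movie(
      h = mv$h %||% 64, w = mv$w %||% 64,
      pixel_size = mv$pixel_size %||% 2, frame_rate = mv$frame_rate %||% 20,
      nframes = mv$nframes %||% 120, pattern = mv$pattern %||% "plane_wave",
      speed = mv$speed %||% 10, direction = mv$direction %||% 0,
      period_ms = mv$period_ms %||% 2000,
      kernel = kernel_from_config(mv$kernel),
      noise_sd = mv$noise_sd %||% 0.02,
      seed = seed + 101 * ci + 1)$movie
    pp <- preprocess_movie(movie)
    flows <- compute_flow_sequence(pp, alpha = hs_alpha, n_iter = hs_iter,
                                   tol = hs_tol, mask_threshold = mask_thr)
    fs <- flow_summary(flows)
    out$mean_magnitude_um_s <- fs$mean_magnitude_um_s
    out$circular_variance <- fs$circular_variance
    utils::write.csv(rose_histogram(flows),
                     file.path(out_dir, paste0(name, "_rose.csv")),
                     row.names = FALSE)
    traces <- extract_traces(movie, grid)
  }
  if (!is.null(cd$traces)) {
    tr <- cd$traces
    traces <- if (!is.null(tr$csv)) read_trace_csv(tr$csv)
    else generate_trace_set(
      n_rois = tr$n_rois %||% 16, n_beats = tr$n_beats %||% 8,
      period_ms = tr$period_ms %||% 2000,
      kernel = kernel_from_config(tr$kernel),
      jitter_sd_ms = tr$jitter_sd_ms %||% 0,
      noise_sd = tr$noise_sd %||% 0,
      frame_rate = tr$frame_rate %||% 20,
      seed = seed + 101 * ci + 2)$traces
  }
  if (!is.null(traces)) {
    traces <- normalize_traces(traces)
    peaks <- detect_peaks(traces, min_prominence_dff = prom,
                          min_separation_ms = sep)
    metrics <- transient_metrics(traces, peaks)
    sync <- tpa_mad(traces, peaks)
    out$tpa_mad_ms <- sync$tpa_mad_ms
    out$median_fwhm_ms <- stats::median(metrics$fwhm_ms, na.rm = TRUE)
    out$median_tau_ms <- stats::median(metrics$tau_ms, na.rm = TRUE)
    write_transient_outputs(metrics, sync,
                            file.path(out_dir, paste0(name, "_transients.csv")),
                            file.path(out_dir, paste0(name, "_summary.json")))
  }
  if (!is.null(cd$motion)) {
    mo <- cd$motion
    mmovie <- if (!is.null(mo$tiff)) read_movie_tiff(mo$tiff)
    else generate_motion_movie(
      h = mo$h %||% 64, w = mo$w %||% 64,
      pixel_size = mo$pixel_size %||% 2, frame_rate = mo$frame_rate %||% 20,
      nframes = mo$nframes %||% 100,
      beat_period_ms = mo$beat_period_ms %||% 1000,
      peak_displacement_px = mo$peak_displacement_px %||% 3,
      contraction_fraction = mo$contraction_fraction %||% 0.5,
      noise_sd = mo$noise_sd %||% 0,
      seed = seed + 101 * ci + 3)$movie
    vt <- velocity_trace(mmovie, alpha = hs_alpha, n_iter = hs_iter,
                         tol = hs_tol)
    cm <- contraction_relaxation_metrics(vt)
    out$mean_contraction_velocity_um_s <- cm$mean_contraction_velocity_um_s
    out$mean_relaxation_velocity_um_s <- cm$mean_relaxation_velocity_um_s
    write_contractility_outputs(vt, cm,
                                file.path(out_dir, paste0(name, "_velocity.csv")),
                                file.path(out_dir,
                                          paste0(name, "_contractility.json")))
  }
  as.data.frame(out)
}

# md5 of the canonical JSON rendering of the configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d condition(s), seed %s, config %s\n",
              nrow(x$metrics), format(x$seed), substr(x$config_hash, 1, 8)))
  print(x$metrics)
  invisible(x)
}
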