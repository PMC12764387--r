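test_that("dF/F0 normalization is robust, scale-invariant and guarded", {
  expect_equal(normalize_dff(rep(7, 50)), rep(0, 50))
  raw <- 100 + 50 * kernel_eval(transient_kernel(100, 300, 1),
                                seq(0, 2000, by = 50)) / 1
  expect_equal(normalize_dff(raw * 3.5), normalize_dff(raw))
  # baseline 100, peak 150: peak dF/F0 about 0.5
  expect_equal(max(normalize_dff(raw)), 0.5, tolerance = 0.02)
  expect_error(normalize_dff(rep(0, 50)), "F0")
  expect_error(normalize_dff(1:5), "samples")
})

test_that("ROI extraction tiles the frame and normalizes per ROI", {
  const <- cw_movie(array(42, dim = c(12, 12, 20)), 20, 2)
  ts <- extract_traces(const, c(3, 3))
  expect_equal(ncol(ts$dff), 9)
  expect_true(all(ts$dff == 0))

  g <- generate_wave_movie(h = 16, w = 16, nframes = 60,
                           pattern = "synchronous", period_ms = 2000,
                           noise_sd = 0, seed = 1)
  one <- extract_traces(g$movie, c(1, 1))
  means <- apply(g$movie$frames, 3, mean)
  expect_equal(one$raw[, 1], means, ignore_attr = TRUE)

  # synchronous movie: every ROI peaks at the ground-truth peak time
  ts4 <- extract_traces(g$movie, c(4, 4))
  pk <- detect_peaks(ts4)
  first <- vapply(pk$peaks, function(p) p$peak_time_ms[1], numeric(1))
  expect_true(all(first == g$truth$peak_times_ms[1, 1]))

  expect_error(extract_traces(const, c(20, 20)), "empty")
})

test_that("peak detection finds each beat once at the right time", {
  expect_equal(nrow(detect_peaks(rep(0, 100),
                                 time_ms = seq(0, 4950, by = 50))$peaks[[1]]),
               0)
  g <- generate_trace_set(n_rois = 1, n_beats = 6, seed = 3)
  ts <- normalize_traces(g$traces)
  pk <- detect_peaks(ts)
  expect_equal(nrow(pk$peaks[[1]]), 6)
  expect_true(all(abs(pk$peaks[[1]]$peak_time_ms -
                        g$truth$peak_times_ms[, 1]) <= 50))
  # same count under moderate noise with prominence at half the amplitude
  gn <- generate_trace_set(n_rois = 1, n_beats = 6, noise_sd = 0.05,
                           seed = 3)
  pkn <- detect_peaks(normalize_traces(gn$traces),
                      min_prominence_dff = 0.5)
  expect_equal(nrow(pkn$peaks[[1]]), 6)
  expect_error(detect_peaks(ts, min_separation_ms = 50), "frame intervals")
})

test_that("FWHM is measured by interpolated half-height crossings", {
  # symmetric triangle of base width 2w has FWHM w
  w <- 400
  t <- seq(0, 2000, by = 50)
  y <- pmax(0, 1 - abs(t - 1000) / w)
  expect_equal(compute_fwhm(y, t, which.max(y)), w)

  k <- transient_kernel(100, 400, 1)
  td <- seq(0, 4000, by = 1)
  expect_equal(compute_fwhm(kernel_eval(k, td), td, 101), kernel_fwhm(k),
               tolerance = 0.01)
  # at 20 frames/s the same kernel is recovered within one frame interval
  t20 <- seq(0, 4000, by = 50)
  y20 <- kernel_eval(k, t20)
  expect_lt(abs(compute_fwhm(y20, t20, which.max(y20)) - kernel_fwhm(k)),
            50)
  # clipped transient: no left crossing -> NA
  expect_true(is.na(compute_fwhm(c(1, 0.9, 0.4, 0.1), c(0, 50, 100, 150), 1)))
})

test_that("decay fitting recovers tau and flags degenerate windows", {
  t <- seq(0, 3000, by = 50)
  y <- exp(-t / 400)
  fit <- fit_decay_tau(y, t, 1)
  expect_equal(fit$tau_ms, 400, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
  # amplitude scaling leaves tau unchanged
  fit_k <- fit_decay_tau(3.7 * y, t, 1)
  expect_equal(fit_k$tau_ms, fit$tau_ms, tolerance = 1e-6)
  # rising window is flagged
  up <- fit_decay_tau(seq(0.1, 1, length.out = 20),
                      seq(0, 950, by = 50), 1)
  expect_true(is.na(up$tau_ms))
  expect_match(up$flag, "non-decaying")
  # too-short window is flagged
  short <- fit_decay_tau(c(1, 0.5, 0.2, 0.05, 0.01, 0.005),
                         seq(0, 250, by = 50), 1)
  expect_true(is.na(short$tau_ms))
})

test_that("mean kinetics on seeded beat trains track the generator truth", {
  # low noise: mean FWHM and tau within 5% of the generating kernel
  k <- transient_kernel()
  est <- sapply(1:3, function(s) {
    g <- generate_trace_set(n_rois = 16, n_beats = 8, noise_sd = 0.02,
                            kernel = k, seed = s)
    m <- transient_metrics(normalize_traces(g$traces),
                           detect_peaks(normalize_traces(g$traces)))
    c(fwhm = mean(m$fwhm_ms, na.rm = TRUE), tau = mean(m$tau_ms, na.rm = TRUE))
  })
  expect_equal(mean(est["fwhm", ]), kernel_fwhm(k), tolerance = 0.05)
  expect_equal(mean(est["tau", ]), k$tau_ms, tolerance = 0.05)
})

test_that("TPA-MAD matches constructed arrival-time spreads exactly", {
  t <- seq(0, 8450, by = 50)
  base <- 100 * (1 + kernel_eval(transient_kernel(),
                                 outer(t, c(500, 2500, 4500, 6500), "-")))
  train <- rowSums(base - 100) + 100

  same <- make_trace_set(t, cbind(train, train, train))
  s0 <- tpa_mad(normalize_traces(same), detect_peaks(normalize_traces(same)))
  expect_equal(s0$tpa_mad_ms, 0)
  expect_equal(s0$n_rois_used, 3)

  # constant offsets {-50, 0, +50} ms: MAD = 50 ms for every beat
  shift <- function(x, k) if (k > 0) c(rep(x[1], k), x[seq_len(length(x) - k)])
    else if (k < 0) c(x[(-k + 1):length(x)], rep(x[length(x)], -k)) else x
  off <- make_trace_set(t, cbind(shift(train, -1), train, shift(train, 1)))
  so <- tpa_mad(normalize_traces(off), detect_peaks(normalize_traces(off)))
  expect_equal(so$tpa_mad_ms, 50)

  # global time shift leaves TPA-MAD unchanged
  sh <- make_trace_set(t, cbind(shift(train, -1 + 3), shift(train, 3),
                                shift(train, 1 + 3)))
  ss <- tpa_mad(normalize_traces(sh), detect_peaks(normalize_traces(sh)))
  expect_equal(ss$tpa_mad_ms, so$tpa_mad_ms)

  # ROI permutation leaves it unchanged
  perm <- make_trace_set(t, cbind(train, shift(train, 1), shift(train, -1)))
  sp <- tpa_mad(normalize_traces(perm), detect_peaks(normalize_traces(perm)))
  expect_equal(sp$tpa_mad_ms, so$tpa_mad_ms)

  one <- make_trace_set(t, cbind(train))
  expect_error(tpa_mad(normalize_traces(one),
                       detect_peaks(normalize_traces(one))), "2 ROIs")
})

test_that("TPA-MAD agrees with the injected jitter sample", {
  # jitter well above the 50 ms frame quantum: estimate within 20% of the
  # empirical MAD of the injected offsets
  r <- sapply(1:6, function(s) {
    g <- generate_trace_set(n_rois = 16, n_beats = 8, jitter_sd_ms = 100,
                            noise_sd = 0.05, seed = s)
    ts <- normalize_traces(g$traces)
    est <- tpa_mad(ts, detect_peaks(ts, min_prominence_dff = 0.5))$tpa_mad_ms
    emp <- median(apply(g$truth$peak_times_ms, 1,
                        function(x) median(abs(x - median(x)))))
    c(est = est, emp = emp)
  })
  expect_equal(mean(r["est", ]), mean(r["emp", ]), tolerance = 0.2)
})

test_that("all trace metrics are invariant to raw-intensity scaling", {
  g <- generate_trace_set(n_rois = 6, n_beats = 5, jitter_sd_ms = 30,
                          noise_sd = 0.03, seed = 11)
  ts1 <- normalize_traces(g$traces)
  ts2 <- g$traces
  ts2$raw <- ts2$raw * 12.3
  ts2 <- normalize_traces(ts2)
  pk1 <- detect_peaks(ts1); pk2 <- detect_peaks(ts2)
  m1 <- transient_metrics(ts1, pk1); m2 <- transient_metrics(ts2, pk2)
  expect_equal(m2$fwhm_ms, m1$fwhm_ms, tolerance = 1e-8)
  expect_equal(m2$tau_ms, m1$tau_ms, tolerance = 1e-6)
  expect_equal(tpa_mad(ts2, pk2)$tpa_mad_ms, tpa_mad(ts1, pk1)$tpa_mad_ms)
})
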