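test_that("preprocessing preserves constants and rejects outliers", {
  const <- cw_movie(array(37, dim = c(16, 16, 20)), 20, 2)
  pp <- preprocess_movie(const)
  expect_equal(pp$frames, const$frames, tolerance = 1e-8)

  # a single-pixel, single-frame impulse is removed by the 3x3 median
  imp <- array(10, dim = c(16, 16, 20))
  imp[8, 8, 10] <- 1000
  med <- cardiowave:::median_filter3(imp[, , 10])
  expect_equal(med[8, 8], 10)

  # the median network agrees exactly with a brute-force 3x3 median
  set.seed(1)
  m <- matrix(runif(30 * 25), 30, 25)
  bf <- m
  for (i in 2:29) for (j in 2:24)
    bf[i, j] <- median(m[(i - 1):(i + 1), (j - 1):(j + 1)])
  f <- cardiowave:::median_filter3(m)
  expect_equal(f[2:29, 2:24], bf[2:29, 2:24])

  expect_error(preprocess_movie(const, temporal_cutoff_hz = 10), "Nyquist")
  expect_error(preprocess_movie(cw_movie(array(1, c(8, 8, 5)), 20, 2)),
               "10 frames")
})

test_that("the temporal low-pass attenuates above-cutoff oscillations", {
  fr <- 20
  t <- (0:119) / fr
  mk <- function(f) {
    a <- array(0, dim = c(8, 8, 120))
    for (k in 1:120) a[, , k] <- 100 + 10 * sin(2 * pi * f * t[k])
    cw_movie(a, fr, 2)
  }
  # steady-state response: measure away from the clip boundaries
  amp <- function(movie) (max(movie$frames[4, 4, 31:90]) -
                            min(movie$frames[4, 4, 31:90])) / 2
  hi <- preprocess_movie(mk(5), temporal_cutoff_hz = 1)
  lo <- preprocess_movie(mk(0.25), temporal_cutoff_hz = 1)
  expect_lt(amp(hi) / amp(lo), 0.1)
})

test_that("Horn-Schunck satisfies its basic identities", {
  set.seed(2)
  a <- matrix(runif(32 * 32), 32)
  z <- horn_schunck(a, a)
  expect_true(all(z$u == 0) && all(z$v == 0))
  # constant intensity offset leaves the flow unchanged
  b <- a + matrix(rnorm(32 * 32, sd = 0.01), 32)
  f1 <- horn_schunck(a, b)
  f2 <- horn_schunck(a + 5, b + 5)
  expect_equal(f2$u, f1$u, tolerance = 1e-10)
  expect_equal(f2$v, f1$v, tolerance = 1e-10)
  expect_error(horn_schunck(a, matrix(NA_real_, 32, 32)), "finite")
})

test_that("Horn-Schunck recovers known sub-pixel and unit shifts", {
  xg <- matrix(rep(1:64, times = 64), 64, 64, byrow = TRUE)
  yg <- t(xg)
  # linear ramp translated by 0.3 px: closed-form gradients, uniform flow
  s <- 0.3
  f <- horn_schunck(0.5 * xg, 0.5 * (xg - s), alpha = 1, n_iter = 2000,
                    tol = 1e-9)
  expect_equal(mean(f$u), s, tolerance = 0.05)
  expect_lt(max(abs(f$v)), 0.02)

  # Gaussian blob translated by (1, 0): mean flow over the blob support
  blob <- function(cx, cy) exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * 6^2))
  fb <- horn_schunck(blob(30, 32), blob(31, 32), alpha = 0.5,
                     n_iter = 4000, tol = 1e-9)
  sup <- blob(30, 32) > 0.1
  expect_equal(mean(fb$u[sup]), 1, tolerance = 0.2)
  expect_equal(mean(fb$v[sup]), 0, tolerance = 0.1)
  # and a shift along +y moves v, not u
  fv <- horn_schunck(blob(32, 30), blob(32, 31), alpha = 0.5,
                     n_iter = 4000, tol = 1e-9)
  expect_equal(mean(fv$v[sup]), 1, tolerance = 0.2)
  expect_lt(abs(mean(fv$u[sup])), 0.1)
})

test_that("flow sequences are masked, reversible and zero for static input", {
  static <- cw_movie(array(rep(matrix(runif(256), 16), 12),
                           c(16, 16, 12)), 20, 2)
  fl <- compute_flow_sequence(static)
  expect_true(all(vapply(fl$fields, function(f)
    all(f$u == 0) && all(f$v == 0), logical(1))))

  g <- generate_wave_movie(h = 32, w = 32, nframes = 50, period_ms = 2000,
                           pattern = "plane_wave", speed = 40,
                           direction = 0, noise_sd = 0, seed = 6)
  fwd <- compute_flow_sequence(g$movie, n_iter = 80)
  rev_frames <- g$movie$frames[, , 50:1]
  bwd <- compute_flow_sequence(cw_movie(rev_frames, 20, 2), n_iter = 80)
  # reversing time negates every vector of the corresponding pair
  expect_equal(bwd$fields[[49]]$u, -fwd$fields[[1]]$u, tolerance = 1e-10)
  expect_equal(bwd$fields[[49]]$v, -fwd$fields[[1]]$v, tolerance = 1e-10)

  # during wavefront transit the masked vectors cluster around the truth
  fs <- flow_summary(fwd)
  expect_lt(ang_diff_deg(fs$circular_mean_rad, g$truth$direction), 15)
})

test_that("flow summaries compute circular statistics and unit scaling", {
  u1 <- matrix(1, 4, 4); v1 <- matrix(1, 4, 4)
  fs <- flow_summary(make_flow_sequence(list(u1), list(v1)),
                     magnitude_floor = 0)
  expect_equal(fs$circular_variance, 0)
  expect_equal(fs$circular_mean_rad, pi / 4)
  expect_equal(fs$mean_magnitude_um_s, sqrt(2))

  # four equal vectors at 0, 90, 180, 270 degrees: zero resultant
  us <- list(matrix(1, 2, 2), matrix(0, 2, 2),
             matrix(-1, 2, 2), matrix(0, 2, 2))
  vs <- list(matrix(0, 2, 2), matrix(1, 2, 2),
             matrix(0, 2, 2), matrix(-1, 2, 2))
  f4 <- flow_summary(make_flow_sequence(us, vs), magnitude_floor = 0)
  expect_equal(f4$circular_variance, 1)

  # doubling the pixel size doubles magnitudes, not angles
  sA <- make_flow_sequence(list(u1), list(v1), pixel_size = 2)
  sB <- make_flow_sequence(list(u1), list(v1), pixel_size = 4)
  fA <- flow_summary(sA, magnitude_floor = 0)
  fB <- flow_summary(sB, magnitude_floor = 0)
  expect_equal(fB$mean_magnitude_um_s, 2 * fA$mean_magnitude_um_s)
  expect_equal(fB$circular_variance, fA$circular_variance)
})

test_that("rose histograms partition the observed phases", {
  set.seed(8)
  th <- runif(1e4, -pi, pi)
  seqn <- make_flow_sequence(list(matrix(cos(th), 100, 100)),
                             list(matrix(sin(th), 100, 100)))
  rose <- rose_histogram(seqn, n_bins = 16, magnitude_floor = 0)
  expect_equal(sum(rose$count), 1e4)
  expect_lte(max(rose$count), 2 * min(rose$count))

  # unidirectional flow concentrates in one bin and its two neighbours
  uni <- make_flow_sequence(list(matrix(1, 10, 10)),
                            list(matrix(0.02, 10, 10)))
  r1 <- rose_histogram(uni, n_bins = 16, magnitude_floor = 0)
  top <- which.max(r1$count)
  nb <- unique(c((top - 2):(top)) %% 16 + 1)
  expect_gte(sum(r1$count[c(top, top %% 16 + 1,
                            (top - 2) %% 16 + 1)]) / sum(r1$count), 0.9)
})

test_that("90-degree rotation rotates the mean direction and nothing else", {
  g <- generate_wave_movie(h = 48, w = 48, nframes = 50, period_ms = 2000,
                           pattern = "plane_wave", speed = 60,
                           direction = pi / 5, noise_sd = 0, seed = 12)
  rotated <- array(0, dim = c(48, 48, 50))
  for (t in 1:50) rotated[, , t] <- rot90(g$movie$frames[, , t])
  f1 <- flow_summary(compute_flow_sequence(g$movie, n_iter = 80))
  f2 <- flow_summary(compute_flow_sequence(cw_movie(rotated, 20, 2),
                                           n_iter = 80))
  # near-exact: the derivative stencil sits on a half-pixel-offset cube
  # corner, so rotating the grid shifts the estimation points slightly
  expect_equal(f2$mean_magnitude_um_s, f1$mean_magnitude_um_s,
               tolerance = 0.02)
  expect_lt(abs(f2$circular_variance - f1$circular_variance), 0.005)
  d <- ang_diff_deg(f2$circular_mean_rad, f1$circular_mean_rad)
  expect_lt(abs(d - 90), 1)
})
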