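test_that("detrend removes the fitted trend and is idempotent", {
  s <- uniform_signal(2 * (0:9) + 1, fs = 1)
  expect_lt(max(abs(detrend(s, "linear")$values)), 1e-9)
  expect_equal(detrend(c(5, 5, 5), "constant"), c(0, 0, 0))
  set.seed(2)
  x <- rnorm(100) + 0.3 * (1:100)
  once <- detrend(x)
  expect_equal(detrend(once), once, tolerance = 1e-12)
  expect_lt(abs(mean(once)), 1e-10)
})

test_that("deduplicate collapses runs only", {
  expect_equal(deduplicate(c(5, 5, 5, 7, 7, 3)), c(5, 7, 3))
  expect_equal(deduplicate(c(1, 2, 1, 2)), c(1, 2, 1, 2))
  expect_equal(deduplicate(rep(4, 10)), 4)
})

test_that("tachogram resampling is exact on constants and never overshoots", {
  rs <- resample_uniform(event_series(rep(1000, 20), "RRi"), 4)
  expect_lt(max(abs(rs$values - 1000)), 1e-9)
  expect_equal(rs$fs, 4)

  rm <- resample_uniform(event_series(seq(800, 1200, length.out = 30), "RRi"), 4)
  expect_false(is.unsorted(rm$values))     # shape preservation

  for (seed in 1:10) {                     # no-overshoot property
    iv <- random_rri(40, seed)
    out <- resample_uniform(event_series(iv, "RRi"), 4)$values
    expect_gte(min(out), min(iv) - 1e-9)
    expect_lte(max(out), max(iv) + 1e-9)
  }
  expect_error(resample_uniform(event_series(c(1000, 900, 1000), "RRi"), 4),
               "4 events")
})

test_that("resampled sinusoidal RRi peaks at the modulation frequency", {
  beats <- cumsum(rep(1, 400))
  iv <- 1000 + 50 * sin(2 * pi * 0.1 * beats)
  tach <- detrend(resample_uniform(event_series(iv, "RRi"), 4))
  S <- psd_estimate(tach, "welch", segment_s = 100)
  expect_lt(abs(S$freqs[which.max(S$psd)] - 0.1), 2 * (S$freqs[2] - S$freqs[1]))
})

test_that("segmentation yields nested prefixes and conserving fifths", {
  s <- uniform_signal(rnorm(1260), fs = 4)   # 315 s at 4 Hz
  segs <- segment_recording(s, segmentation_plan("nested", minutes = 1:5))
  expect_equal(vapply(segs, length, numeric(1)), c(240, 480, 720, 960, 1200))
  expect_true(all(vapply(segs, function(g) g$t0 == s$t0, logical(1))))
  expect_error(segment_recording(s, segmentation_plan("nested", minutes = c(1, 6))),
               "shorter")

  u <- uniform_signal(rnorm(1000), fs = 10)
  fifths <- segment_recording(u, segmentation_plan("equal_fifths"))
  expect_equal(vapply(fifths, length, numeric(1)), rep(200, 5))
  expect_equal(unlist(lapply(fifths, function(g) g$values)), u$values)

  es <- event_series(rep(1000, 180), "RRi")  # beats at 1..180 s
  pre <- segment_recording(es, segmentation_plan("nested", minutes = 1:2))
  expect_equal(length(pre[[1]]$intervals), 59)   # time < 60 s, half-open
  expect_equal(length(pre[[2]]$intervals), 119)
})

test_that("finegrid interpolation inserts points per the stated rules", {
  expect_equal(finegrid_interpolate(c(0, 2), "linear", 1), c(0, 1, 2))
  expect_equal(finegrid_interpolate(c(0, 2), "nearest", 1), c(0, 0, 2))
  expect_equal(finegrid_interpolate(c(0, 3), "linear", 2), c(0, 1, 2, 3))
  expect_error(finegrid_interpolate(c(0, 1), "linear", 4), "n_points")
  # decimation by 2 inverts one-point linear refinement
  x <- rnorm(25)
  fg <- finegrid_interpolate(x, "linear", 1)
  expect_equal(length(fg), 25 + 24)
  expect_identical(fg[seq(1, length(fg), by = 2)], x)
})

test_that("coloured noise hits the target SNR and spectral slopes", {
  s <- uniform_signal(sin(2 * pi * (1:512) / 64), fs = 8)
  expect_identical(add_noise(s, "white", Inf), s)
  noisy <- add_noise(s, "white", snr_db = 10, seed = 4)
  snr <- 10 * log10(var(s$values) / var(noisy$values - s$values))
  expect_equal(snr, 10, tolerance = 1e-6)
  expect_identical(add_noise(s, "pink", 5, seed = 9)$values,
                   add_noise(s, "pink", 5, seed = 9)$values)

  base <- uniform_signal(rnorm(2^16), fs = 1)
  w <- add_noise(base, "white", -40, seed = 1)$values - base$values
  p <- add_noise(base, "pink", -40, seed = 1)$values - base$values
  expect_lt(abs(psd_slope(w) - 0), 0.1)
  expect_lt(abs(psd_slope(p) - (-1)), 0.1)
  expect_error(add_noise(uniform_signal(rep(1, 8), 1), "white", 3), "variance")
})

test_that("amplitude transforms match their definitions", {
  expect_equal(transform_amplitude(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  expect_equal(transform_amplitude(c(1, 3, 2), "binarize_b"), c(1, -1))
  set.seed(5)
  for (i in 1:5) {
    z <- transform_amplitude(rnorm(30, 7, 3), "zscore")
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  expect_equal(transform_amplitude(c(1, 5, 2, 8), "binarize_a"), c(0, 1, 0, 1))
  r <- transform_amplitude(c(10, 11, 12, 14), "robust")
  expect_equal(median(r), 0)
  d <- c(1, 1.1, 5, 5.1)                       # one large jump
  expect_equal(transform_amplitude(d, "binarize_c"), c(0, 1, 0))
  expect_error(transform_amplitude(rep(3, 5), "zscore"), "constant")
  expect_error(transform_amplitude(rep(3, 5), "minmax"), "constant")
})

test_that("reverse arrangements count trends and ignore monotone relabelling", {
  expect_equal(reverse_arrangement_test(1:10)$A, 0)
  expect_equal(reverse_arrangement_test(10:1)$A, 45)        # N(N-1)/2
  # E[A] = N(N-1)/4 = 22.5 for N = 10: z = 0 at that value
  mid <- reverse_arrangement_test(c(2, 4, 1, 3, 6, 5, 8, 7, 10, 9))
  expect_equal((mid$A - 22.5) / mid$z, sqrt(10 * 25 * 9 / 72), tolerance = 1e-12)
  set.seed(6)
  x <- rnorm(50)
  expect_equal(reverse_arrangement_test(exp(x))$A, reverse_arrangement_test(x)$A)
  expect_true(reverse_arrangement_test(1:20 + rnorm(20, 0, 0.1))$nonstationary)
})

test_that("breath intervals recover pacer timing and ratios", {
  b <- extract_breath_intervals(gen_pacer(6, 0.4, 315))
  tol <- 1 / 32 + 1e-9                          # one sample at 32 Hz
  expect_lt(max(abs(b$IN$intervals - 4)), tol)
  expect_lt(max(abs(b$OUT$intervals - 6)), tol)
  expect_lt(max(abs(b$PP$intervals - 10)), tol)
  expect_equal(mean(b$ratio), 1.5, tolerance = 0.02)

  s <- uniform_signal(sin(2 * pi * 0.1 * seq(0, 120, by = 1 / 32)), 32)
  expect_equal(mean(extract_breath_intervals(s)$ratio), 1, tolerance = 0.02)

  s10 <- uniform_signal(10 * s$values, 32)      # amplitude invariance
  expect_equal(extract_breath_intervals(s10)$PP$intervals,
               extract_breath_intervals(s)$PP$intervals)
  expect_error(extract_breath_intervals(
    uniform_signal(rep(c(0, 1e-4), 200), 32)), "cycles")
})
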