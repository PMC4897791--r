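test_that("hand-computed shape measures match their definitions", {
  ct <- f0_contour(frame_times = c(0, 0.04, 0.08), f0 = c(10, 12, 11))
  sf <- extract_contour_features(ct)
  expect_equal(sf$cofm, 3 / 10000)
  expect_equal(sf$jitter_factor, 100 * (3 / 11) / 2)
  expect_equal(sf$freq_variability_index, 10 * 1 / 11^2)
  expect_equal(sf$min_freq, 10)
  expect_equal(sf$max_freq, 12)
  expect_equal(sf$time_min_to_max, 0.04)
})

test_that("a constant contour has zero modulation and zero slopes", {
  ct <- f0_contour(frame_times = (0:4) * 0.04, f0 = rep(11, 5))
  sf <- extract_contour_features(ct)
  expect_equal(sf$cofm, 0)
  expect_equal(sf$jitter_factor, 0)
  expect_equal(sf$freq_variability_index, 0)
  expect_equal(sf$start_slope, 0)
  expect_equal(sf$middle_slope, 0)
  expect_equal(sf$final_slope, 0)
  # ties in min/max resolve to the first frame
  expect_equal(sf$min_freq_loc, 0)
})

test_that("all features equal the brute-force transcription on short contours", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    t <- cumsum(c(0.1, rep(0.04, n - 1)))
    f <- runif(n, 8, 20)
    sf <- extract_contour_features(f0_contour(t, f))
    or <- oracle_contour_features(t, f)
    for (nm in names(or))
      expect_equal(sf[[nm]], or[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("modulation measures are non-negative and vanish only for constant contours", {
  set.seed(7)
  for (rep in 1:20) {
    f <- runif(6, 8, 20)
    sf <- extract_contour_features(f0_contour((0:5) * 0.04, f))
    expect_gte(sf$cofm, 0)
    expect_gte(sf$jitter_factor, 0)
    expect_gte(sf$freq_variability_index, 0)
    if (var(f) > 0) {
      expect_gt(sf$cofm, 0)
      expect_gt(sf$freq_variability_index, 0)
    }
  }
})

test_that("linear upsampling preserves extremes and total modulation", {
  set.seed(8)
  t <- (0:9) * 0.04
  f <- runif(10, 8, 20)
  t2 <- seq(t[1], t[10], by = 0.02)
  f2 <- approx(t, f, xout = t2)$y
  a <- extract_contour_features(f0_contour(t, f))
  b <- extract_contour_features(f0_contour(t2, f2))
  expect_equal(a$min_freq, b$min_freq)
  expect_equal(a$max_freq, b$max_freq)
  expect_equal(a$cofm, b$cofm, tolerance = 1e-12)  # sum-based, conserved
  expect_equal(a$mean_freq, b$mean_freq, tolerance = 0.05 * a$mean_freq)
})

test_that("tracking is invariant to waveform amplitude scaling", {
  w <- synthesize_rumble(synth_call_spec(10, 14, 11, duration = 4, seed = 2))
  w2 <- w
  w2$samples <- w$samples * 0.05
  a <- extract_contour_features(trace_f0(w))
  b <- extract_contour_features(trace_f0(w2))
  expect_equal(as.numeric(a[1, ]), as.numeric(b[1, ]), tolerance = 1e-9)
})

test_that("a linear sweep recovers its endpoints", {
  # 10 -> 20 Hz over 6 s (mid = 15)
  w <- synthesize_rumble(synth_call_spec(10, 15, 20, duration = 6,
                                         formant_freqs = c(25, 77.1),
                                         noise_snr = 40, seed = 4))
  sf <- extract_contour_features(trace_f0(w))
  native_bin <- 1 / 0.3
  expect_lt(abs(sf$start_freq - 10), native_bin)
  expect_lt(abs(sf$finish_freq - 20), native_bin)
})

test_that("silence and degenerate contours error out cleanly", {
  silent <- structure(list(samples = rep(0, 8000), sample_rate = 4000),
                      class = "rumble_wave")
  expect_error(trace_f0(silent), "untraceable")
  expect_error(trace_f0(structure(list(samples = rep(0, 10), sample_rate = 4000),
                                  class = "rumble_wave")), "shorter")
  ct <- f0_contour(c(0, 0.04), c(10, 11))
  expect_error(extract_contour_features(ct), "at least 3")
})

test_that("contour export yields a two-column table of voiced frames", {
  ct <- f0_contour((0:4) * 0.04, c(10, 11, 12, 11, 10),
                   voiced_mask = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  tab <- contour_to_table(ct)
  expect_named(tab, c("time_s", "f0_hz"))
  expect_equal(nrow(tab), 4)
})
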