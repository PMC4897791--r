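test_that("call specification rejects invalid parameters", {
  expect_error(synth_call_spec(duration = 0), "duration")
  expect_error(synth_call_spec(formant_freqs = c(77, 21.5)), "ascending")
  expect_error(synth_call_spec(f0_start = 25, f0_mid = 25, f0_end = 25,
                               formant_freqs = c(21.5, 77)), "below the first formant")
  expect_error(synth_call_spec(formant_freqs = c(100, 900), sample_rate = 2000),
               "4 times")
  expect_error(synth_call_spec(formant_freqs = c(100)), "two formant")
})

test_that("synthesized waveform is finite, normalized and of the right length", {
  w <- synthesize_rumble(synth_call_spec(12, 12, 12, duration = 2, seed = 1))
  expect_true(all(is.finite(w$samples)))
  expect_equal(max(abs(w$samples)), 0.95, tolerance = 1e-12)
  expect_equal(length(w$samples), 2 * w$sample_rate)
  expect_equal(w$ground_truth$formants, c(21.5, 77.1))
})

test_that("a single-harmonic unfiltered call is a pure tone at f0", {
  sp <- synth_call_spec(12, 12, 12, duration = 4, harmonic_count = 1,
                        noise_snr = Inf, seed = 1)
  w <- synthesize_rumble(sp, apply_filter = FALSE)
  # spectral peak of the whole call sits at f0
  n <- length(w$samples)
  spec <- Mod(fft(w$samples * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / n))))
  freqs <- (seq_len(n) - 1) * w$sample_rate / n
  peak <- freqs[which.max(spec[freqs < w$sample_rate / 2])]
  expect_equal(peak, 12, tolerance = 0.3)
})

test_that("constant-f0 rumble round-trips through the tracker", {
  w <- synthesize_rumble(synth_call_spec(12, 12, 12, duration = 6,
                                         noise_snr = 40, seed = 3))
  ct <- trace_f0(w)
  f <- ct$f0[ct$voiced_mask]
  expect_gt(length(f), 100)
  expect_true(all(abs(f - 12) < 0.5))
})

test_that("feature cohort sampling is seeded and byte-reproducible", {
  cs <- table3_cohort_spec(seed = 5)
  a <- sample_feature_cohort(cs)
  b <- sample_feature_cohort(cs)
  expect_identical(a, b)
  cs2 <- table3_cohort_spec(seed = 6)
  expect_false(identical(sample_feature_cohort(cs2), a))
})

test_that("zero-SD cohort collapses onto the group mean vectors", {
  m <- rbind(g1 = c(f1 = 20, f2 = 70), g2 = c(f1 = 30, f2 = 100))
  s <- rbind(g1 = c(0, 0), g2 = c(0, 0))
  cs <- cohort_spec(m, s, n_individuals = 2, calls_per_ind = c(3, 3),
                    individual_effect_sd = 0, seed = 1)
  out <- sample_feature_cohort(cs)
  expect_true(all(out$f1[out$maturity_group == "g1"] == 20))
  expect_true(all(out$f2[out$maturity_group == "g2"] == 100))
})

test_that("cohort moments converge to the specified reference values", {
  # law-of-large-numbers check at n = 10^4 per group, no individual effects
  ref <- table3_reference()
  m <- rbind(group1 = ref$mean1, group2 = ref$mean2)
  s <- rbind(group1 = ref$sd1, group2 = ref$sd2)
  colnames(m) <- colnames(s) <- ref$feature
  cs <- cohort_spec(m, s, n_individuals = 1,
                    calls_per_ind = list(1e4, 1e4),
                    individual_effect_sd = 0, seed = 11)
  out <- sample_feature_cohort(cs)
  g1 <- out[out$maturity_group == "group1", ]
  se <- ref$sd1 / sqrt(1e4)
  for (j in seq_along(ref$feature)) {
    expect_lt(abs(mean(g1[[ref$feature[j]]]) - ref$mean1[j]), 3 * se[j])
    expect_lt(abs(sd(g1[[ref$feature[j]]]) - ref$sd1[j]), 3 * ref$sd1[j] / sqrt(2e4))
  }
  g2 <- out[out$maturity_group == "group2", ]
  expect_lt(abs(mean(g2$formant2) - 104.53), 3 * 7.7 / sqrt(1e4))
})

test_that("cohort specification rejects negative dispersions", {
  m <- rbind(g1 = c(a = 1), g2 = c(a = 2))
  expect_error(cohort_spec(m, rbind(g1 = -1, g2 = 1)), "non-negative")
})

test_that("waveform cohort writes audio, annotations and ground truth that agree", {
  dir <- withr::local_tempdir()
  m <- rbind(g1 = c(formant1 = 21.53, formant2 = 77.14, max_freq = 13.81,
                    min_freq = 9.91, finish_freq = 10.41))
  s <- rbind(g1 = c(2.0, 7.6, 1.6, 1.2, 1.5) / 4)
  cs <- cohort_spec(m, s, n_individuals = 2, calls_per_ind = c(2, 2),
                    individual_effect_sd = 0.2, seed = 4)
  out <- make_waveform_cohort(cs, dir, duration_range = c(3, 4))
  expect_equal(nrow(out$annotations), 4)
  expect_true(all(file.exists(file.path(dir, out$annotations$file))))
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  ann <- read_annotations(file.path(dir, "annotations.csv"), dir)
  expect_equal(nrow(ann), 4)
  # ground truth mirrors the sampled features
  feat <- sample_feature_cohort(cs)
  expect_equal(out$ground_truth$formant1, feat$formant1)
  expect_equal(out$ground_truth$f0_mid, feat$max_freq)
})
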