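# Brute-force transcriptions used as independent oracles.

# contour features computed directly from their verbal definitions
oracle_contour_features <- function(t, f) {
  n <- length(f)
  dur <- t[n] - t[1]
  adiff <- sum(abs(diff(f)))
  thirds <- findInterval(t, t[1] + dur * c(1, 2) / 3) + 1
  rt <- seq(t[1], t[n], length.out = 61)
  rf <- approx(t, f, xout = rt)$y
  list(
    start_freq = f[1],
    mid_freq = f[which.min(abs(t - (t[1] + dur / 2)))],
    finish_freq = f[n],
    min_freq = min(f), max_freq = max(f), mean_freq = mean(f),
    mean_third1 = mean(f[thirds == 1]),
    mean_third2 = mean(f[thirds == 2]),
    mean_third3 = mean(f[thirds == 3]),
    duration = dur,
    min_freq_loc = t[which.min(f)] - t[1],
    max_freq_loc = t[which.max(f)] - t[1],
    time_min_to_max = abs(t[which.max(f)] - t[which.min(f)]),
    cofm = adiff / 10000,
    jitter_factor = 100 * (adiff / mean(f)) / (n - 1),
    freq_variability_index = 10 * var(f) / mean(f)^2,
    start_slope = (rf[20] - rf[1]) / (rt[20] - rt[1]),
    middle_slope = (rf[40] - rf[20]) / (rt[40] - rt[20]),
    final_slope = (rf[60] - rf[40]) / (rt[60] - rt[40]))
}

# PIC from its definition, small-sample-corrected within-CV
oracle_pic <- function(x, ind, correct = TRUE) {
  cvw <- sapply(split(x, ind), function(xi) {
    k <- if (correct) 1 + 1 / (4 * length(xi)) else 1
    100 * k * sd(xi) / mean(xi)
  })
  cvb <- 100 * sd(x) / mean(x)
  list(mean_cv_within = mean(cvw), cv_between = cvb, pic = cvb / mean(cvw))
}

# one-way two-group F via explicit sums of squares
oracle_anova_f <- function(x, g) {
  g <- factor(g)
  gm <- tapply(x, g, mean)
  ssb <- sum(table(g) * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  (ssb / 1) / (ssw / (length(x) - 2))
}

# canonical synthetic fixture: modulated contour, group-1 formants
make_fixture_wave <- function(seed = 1, noise_snr = 40,
                              formants = c(21.5, 77.1),
                              f0 = c(10, 14, 11), duration = 5) {
  synthesize_rumble(synth_call_spec(
    f0[1], f0[2], f0[3], duration = duration,
    formant_freqs = formants, noise_snr = noise_snr, seed = seed))
}
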