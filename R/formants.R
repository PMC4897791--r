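#' Estimate formant frequencies of a rumble
#'
#' Downsamples the call to 2000 Hz (zero-phase low-pass followed by
#' linear-interpolation resampling) and locates the vocal tract
#' resonances as spectral-envelope peaks over 0-500 Hz.
#'
#' In these calls the fundamental (8-20 Hz) is only 2-3 times below the
#' first resonance, so a single long-window spectrum samples the vocal
#' tract envelope only at sparse, dwell-weighted harmonic lines, and the
#' peak of a classical whole-call LPC envelope is biased toward
#' whichever harmonic lingers near the resonance. The default
#' `method = "harmonic"` therefore reconstructs the envelope from the
#' harmonics themselves: the fundamental contour is traced
#' ([trace_f0()]) and each harmonic's magnitude is measured in
#' overlapping frames - natural frequency modulation sweeps the
#' harmonics across the resonances, so over the call the envelope is
#' sampled densely. Two frame lengths are combined (short frames below
#' `split_hz`, where the narrow first resonance must be tracked through
#' fast-swept excitation; long frames above, where closely spaced upper
#' harmonics need frequency resolution), the log-magnitude samples are
#' averaged in 1-Hz bins, lightly smoothed, and equalized by removing
#' the linear spectral tilt of the source rolloff. Formants are the
#' local maxima of this envelope with at least `min_prominence_db`
#' prominence and `min_separation_hz` spacing, ascending, ties broken
#' toward the lower frequency, restricted to the harmonically covered
#' range. An LPC all-pole smooth of the same envelope (order
#' `lpc_order`, autocorrelation method) is fitted and returned as the
#' `envelope` element.
#'
#' `method = "lpc"` instead applies the classical recipe directly: a
#' Hamming window over the whole call, LPC by the autocorrelation
#' (Levinson-Durbin) method, and peak-picking of the resulting envelope.
#' It is retained for broadband recordings where the envelope is well
#' sampled; on strongly harmonic infrasonic calls it is biased (see
#' above). No pre-emphasis is applied in either method.
#'
#' @param wave A `rumble_wave`; at least 0.5 s long after downsampling.
#' @param lpc_order LPC model order (default 16; order 8 is the common
#'   low-resolution alternative).
#' @param band Analysis band in Hz (default `c(0, 500)`).
#' @param max_formants Return at most this many peaks (default 4).
#' @param min_prominence_db,min_separation_hz Peak-picking thresholds.
#' @param method `"harmonic"` (default) or `"lpc"` (see Details).
#' @param f_lo,f_hi Fundamental search band passed to [trace_f0()].
#' @param split_hz Crossover between the short-frame and long-frame
#'   harmonic envelopes.
#' @return A list of class `formant_estimate` with `formants` (Hz,
#'   ascending), `dispersion_f1f2` (F2 - F1), `lpc_order`, `band`,
#'   `method`, and `envelope` (data frame `freq_hz`, `level_db`: the
#'   LPC-smoothed envelope). Errors with "unmeasurable formants" when
#'   fewer than two peaks are found or the harmonic structure cannot be
#'   resolved.
#' @export
estimate_formants <- function(wave, lpc_order = 16, band = c(0, 500),
                              max_formants = 4,
                              min_prominence_db = 4,
                              min_separation_hz = 10,
                              method = c("harmonic", "lpc"),
                              f_lo = 5, f_hi = 50, split_hz = 40) {
  method <- match.arg(method)
  fs_target <- 2000
  x <- wave$samples
  fs <- wave$sample_rate
  if (fs > fs_target) {
    bf <- signal::butter(8, 0.9 * (fs_target / 2) / (fs / 2))
    x <- signal::filtfilt(bf, x)
    t_old <- (seq_along(x) - 1) / fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / fs_target)
    x <- stats::approx(t_old, x, xout = t_new)$y
    fs <- fs_target
  } else if (fs < fs_target) {
    stop("sample rate below 2000 Hz not supported")
  }
  if (length(x) < 0.5 * fs)
    stop("call too short for formant analysis (< 0.5 s at 2000 Hz)")
  x <- x - mean(x)

  if (method == "lpc") {
    win <- 0.54 - 0.46 * cos(2 * pi * seq_along(x) / (length(x) + 1))
    a <- lpc_autocorrelation(x * win, lpc_order)
    grid <- seq(max(band[1], 0.25), band[2], by = 0.25)
    env_db <- lpc_envelope_db(a, fs, grid)
    peaks <- find_prominent_peaks(grid, env_db, 1, min_separation_hz)
    if (length(peaks) < 2)
      stop("unmeasurable formants: fewer than 2 LPC peaks in band")
    peaks <- peaks[seq_len(min(length(peaks), max_formants))]
    return(structure(list(formants = peaks,
                          dispersion_f1f2 = peaks[2] - peaks[1],
                          lpc_order = lpc_order, band = band,
                          method = method,
                          envelope = data.frame(freq_hz = grid,
                                                level_db = env_db)),
                     class = "formant_estimate"))
  }

  contour <- tryCatch(
    trace_f0(structure(list(samples = x, sample_rate = fs),
                       class = "rumble_wave"), f_lo = f_lo, f_hi = f_hi),
    error = function(e) NULL)
  if (is.null(contour))
    stop("unmeasurable formants: no harmonic structure (untraceable call)")
  env <- harmonic_envelope(x, fs, contour, band, split_hz = split_hz)
  grid <- env$grid
  # 5-point moving-average smooth, then remove the linear source tilt
  Es <- stats::filter(env$level_db, rep(1 / 5, 5), sides = 2)
  Es[is.na(Es)] <- env$level_db[is.na(Es)]
  Es <- as.numeric(Es)
  inside <- grid >= env$coverage[1] & grid <= env$coverage[2]
  tilt <- stats::lm.fit(cbind(1, grid[inside]), Es[inside])$coefficients
  Ed <- Es - (tilt[1] + tilt[2] * grid)
  peaks <- find_prominent_peaks(grid, Ed, min_prominence_db,
                                min_separation_hz)
  peaks <- peaks[peaks >= env$coverage[1] - 2 & peaks <= env$coverage[2] + 2]
  if (length(peaks) < 2)
    stop("unmeasurable formants: fewer than 2 envelope peaks in band")
  peaks <- peaks[seq_len(min(length(peaks), max_formants))]
  a <- lpc_from_power_spectrum(10^(env$level_db / 10), lpc_order)
  g2 <- seq(max(band[1], 0.25), band[2] - 1, by = 0.25)
  structure(list(formants = peaks,
                 dispersion_f1f2 = peaks[2] - peaks[1],
                 lpc_order = lpc_order, band = band, method = method,
                 envelope = data.frame(
                   freq_hz = g2,
                   level_db = lpc_envelope_db(a, 2 * band[2], g2))),
            class = "formant_estimate")
}

# Sample the spectral envelope at the harmonics of the traced
# fundamental across overlapping frames, combining a short-frame
# analysis below split_hz with a long-frame analysis above, average the
# window-gain-normalized log-magnitudes in 1-Hz bins, and interpolate
# onto a 1-Hz grid over [0, band_hi]. Returns the grid, the envelope in
# dB and the harmonically covered frequency range.
harmonic_envelope <- function(x, fs, contour, band, split_hz = 40,
                              frame_short = 0.25, frame_long = 0.5,
                              hop_s = 0.05) {
  band_hi <- band[2]
  tc <- contour$frame_times[contour$voiced_mask]
  fc <- contour$f0[contour$voiced_mask]
  sample_env <- function(frame_s) {
    n_frame <- min(round(frame_s * fs), length(x))
    hop <- max(1L, round(hop_s * fs))
    nfft <- 2^ceiling(log2(max(n_frame, fs / 0.25)))
    win <- 0.54 - 0.46 * cos(2 * pi * seq_len(n_frame) / (n_frame + 1))
    wsum <- sum(win)
    freqs <- (seq_len(nfft %/% 2) - 1) * fs / nfft
    starts <- seq(1, length(x) - n_frame + 1, by = hop)
    pts_f <- pts_a <- numeric(0)
    for (s in starts) {
      tmid <- (s - 1 + n_frame / 2) / fs
      if (tmid < min(tc) || tmid > max(tc)) next
      f0 <- stats::approx(tc, fc, xout = tmid)$y
      seg <- x[s + seq_len(n_frame) - 1]
      seg <- (seg - mean(seg)) * win
      spec <- Mod(stats::fft(c(seg, numeric(nfft - n_frame))))[seq_len(nfft %/% 2)] / wsum
      for (k in seq_len(floor(band_hi / f0))) {
        fk <- k * f0
        wnd <- which(freqs > fk - 0.35 * f0 & freqs < fk + 0.35 * f0)
        if (!length(wnd)) next
        j <- wnd[which.max(spec[wnd])]
        pts_f <- c(pts_f, freqs[j])
        pts_a <- c(pts_a, max(spec[j], 1e-15))
      }
    }
    list(f = pts_f, a = pts_a)
  }
  ps <- sample_env(frame_short)
  pl <- sample_env(frame_long)
  keep_s <- ps$f < split_hz
  keep_l <- pl$f >= split_hz
  pts_f <- c(ps$f[keep_s], pl$f[keep_l])
  pts_a <- c(ps$a[keep_s], pl$a[keep_l])
  if (length(pts_f) < 10)
    stop("unmeasurable formants: too few harmonic samples")
  bins <- floor(pts_f)
  env_a <- tapply(20 * log10(pts_a), bins, mean)
  env_f <- as.numeric(names(env_a)) + 0.5
  grid <- seq(0, band_hi, by = 1)
  E <- stats::approx(env_f, as.numeric(env_a), xout = grid, rule = 2)$y
  list(grid = grid, level_db = E, coverage = range(pts_f))
}

# LPC fit to a sampled one-sided power spectrum [0, Nyquist]:
# autocorrelation by inverse FFT of the symmetrized spectrum, then the
# Toeplitz normal equations
lpc_from_power_spectrum <- function(p, order) {
  pfull <- c(p, rev(p[c(-1, -length(p))]))
  r <- Re(stats::fft(pfull, inverse = TRUE)) / length(pfull)
  r[1] <- r[1] * (1 + 1e-9)
  solve(stats::toeplitz(r[1:order]), r[2:(order + 1)])
}

# LPC coefficients (a1..ap of A(z) = 1 - sum a_k z^-k) by the
# autocorrelation method, solved via the Toeplitz normal equations
lpc_autocorrelation <- function(x, p) {
  n <- length(x)
  r <- sapply(0:p, function(k) sum(x[1:(n - k)] * x[(1 + k):n]))
  if (r[1] <= 0) stop("zero-energy signal")
  # slight regularization keeps the Toeplitz system well-posed
  r[1] <- r[1] * (1 + 1e-9)
  solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
}

# all-pole envelope level in dB on a frequency grid
lpc_envelope_db <- function(a, fs, freqs) {
  p <- length(a)
  z <- exp(-2i * pi * outer(freqs / fs, seq_len(p)))
  h <- 1 / abs(1 - as.vector(z %*% a))
  20 * log10(pmax(h, 1e-12))
}

# local maxima with a simple prominence criterion and minimum spacing;
# refined by parabolic interpolation; ties broken toward lower frequency
find_prominent_peaks <- function(x, y, min_prom, min_sep) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(idx)) return(numeric(0))
  prom <- vapply(idx, function(i) {
    left <- y[1:i]; right <- y[i:n]
    hl <- which(left > y[i]); hr <- which(right > y[i])
    lo_l <- if (length(hl)) min(left[max(hl):i]) else min(left)
    lo_r <- if (length(hr)) min(right[1:min(hr)]) else min(right)
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- idx[prom >= min_prom]
  if (!length(keep)) return(numeric(0))
  keep <- keep[order(x[keep])]
  # enforce minimum separation, keeping the higher peak (lower freq on tie)
  sel <- integer(0)
  for (i in keep) {
    if (length(sel) && x[i] - x[sel[length(sel)]] < min_sep) {
      if (y[i] > y[sel[length(sel)]]) sel[length(sel)] <- i
    } else sel <- c(sel, i)
  }
  vapply(sel, function(i) {
    if (i > 1 && i < n) {
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      d <- if (abs(denom) > 1e-12) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
      x[i] + max(-0.5, min(0.5, d)) * (x[2] - x[1])
    } else x[i]
  }, numeric(1))
}

#' Estimated vocal tract length from formant dispersion
#'
#' Uniform-tube model: a tube of length L open at one end has resonances
#' spaced by c/(2L), so L = c / (2 * (f2 - f1)).
#'
#' @param f1,f2 First and second formant frequencies (Hz), `f2 > f1 > 0`.
#' @param c Speed of sound in m/s (default 350, the warm-air convention).
#' @return Estimated vocal tract length in metres. Vectorized.
#' @examples
#' estimate_vtl(21.53, 77.14)  # ~ 3.15 m
#' @export
estimate_vtl <- function(f1, f2, c = 350) {
  if (any(f1 <= 0)) stop("f1 must be positive")
  if (any(f2 <= f1)) stop("f2 must exceed f1")
  c / (2 * (f2 - f1))
}

#' Monte-Carlo distribution of per-call vocal tract length
#'
#' Draws (F1, F2) pairs from independent Gaussians, discards draws with
#' F2 <= F1, and returns the per-call VTL values. Because 1/x is convex,
#' the mean per-call VTL exceeds the VTL of the mean formants (Jensen's
#' inequality); with realistic formant SDs the inflation is about 2%.
#'
#' @param n Number of draws.
#' @param f1_mean,f1_sd,f2_mean,f2_sd Formant distribution parameters (Hz).
#' @param c Speed of sound (m/s).
#' @param seed Integer seed.
#' @return Numeric vector of VTL values (m), length <= `n`.
#' @export
simulate_vtl <- function(n, f1_mean, f1_sd, f2_mean, f2_sd,
                         c = 350, seed = 1L) {
  withr_seed(seed, {
    f1 <- stats::rnorm(n, f1_mean, f1_sd)
    f2 <- stats::rnorm(n, f2_mean, f2_sd)
    keep <- f2 > f1 & f1 > 0
    estimate_vtl(f1[keep], f2[keep], c = c)
  })
}
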