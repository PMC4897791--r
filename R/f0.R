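#' Construct a fundamental-frequency contour object
#'
#' @param frame_times Frame-centre times in seconds, strictly increasing.
#' @param f0 Fundamental frequency per frame (Hz).
#' @param frame_size,step Analysis frame size and hop in seconds.
#' @param voiced_mask Logical per frame; defaults to all voiced.
#' @return An object of class `f0_contour`.
#' @export
f0_contour <- function(frame_times, f0, frame_size = 0.3, step = 0.04,
                       voiced_mask = rep(TRUE, length(f0))) {
  stopifnot(length(frame_times) == length(f0),
            length(voiced_mask) == length(f0))
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  if (any(f0[voiced_mask] <= 0, na.rm = TRUE))
    stop("voiced f0 values must be positive")
  structure(list(frame_times = frame_times, f0 = f0,
                 frame_size = frame_size, step = step,
                 voiced_mask = voiced_mask),
            class = "f0_contour")
}

#' Trace the fundamental-frequency contour of a rumble
#'
#' Computes a short-time Fourier spectrogram (Hamming window, 300 ms
#' frames, 40 ms hop by default; zero-padded so the FFT bin spacing is at
#' most 0.5 Hz) and, per frame, picks the dominant spectral peak inside
#' the search band, refined by parabolic interpolation. Frames whose
#' in-band peak fails a prominence test against the median in-band
#' level, or whose energy is negligible, are flagged unvoiced.
#'
#' Because the first vocal tract resonance sits near the second harmonic
#' in these calls, the raw in-band argmax is prone to octave errors; each
#' frame therefore also checks the subharmonics at 1/2 and 1/3 of the
#' peak frequency and steps down whenever the subharmonic is a genuine
#' spectral line carrying at least `subharmonic_ratio` of the peak
#' magnitude. Octave errors can nevertheless persist in frames where the
#' resonance sits exactly on the second harmonic and buries the
#' fundamental; the tracker therefore anchors the contour at the voiced
#' frame with the strongest harmonic support (number of spectral lines
#' found at integer multiples of the frame's candidate) and propagates
#' outward from that anchor under a maximum-jump continuity constraint
#' of two native (1/frame_size) bins between adjacent frames, snapping
#' each frame to the strongest spectral line near its neighbour's value.
#'
#' @param wave A `rumble_wave` (list with `samples` and `sample_rate`).
#' @param frame_size Frame length in seconds (default 0.300).
#' @param step Hop size in seconds (default 0.040).
#' @param f_lo,f_hi Search band for the fundamental in Hz.
#' @param prominence_db Minimum excess of the frame peak over the median
#'   in-band magnitude, in dB, for the frame to count as voiced.
#' @param subharmonic_ratio Minimum magnitude of a subharmonic, relative
#'   to the dominant peak, for the tracker to prefer it as the
#'   fundamental.
#' @return An `f0_contour`. Errors with "untraceable call" if no frame is
#'   voiced.
#' @export
trace_f0 <- function(wave, frame_size = 0.3, step = 0.04,
                     f_lo = 5, f_hi = 50, prominence_db = 10,
                     subharmonic_ratio = 0.05) {
  x <- wave$samples
  fs <- wave$sample_rate
  n_frame <- round(frame_size * fs)
  if (length(x) < n_frame)
    stop("waveform shorter than one analysis frame")
  hop <- round(step * fs)
  starts <- seq(1, length(x) - n_frame + 1, by = hop)
  nfft <- 2^ceiling(log2(max(n_frame, fs / 0.5)))
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(n_frame) / (n_frame + 1))
  freqs <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  band <- which(freqs >= f_lo & freqs <= f_hi)
  peak_f <- peak_mag <- med_mag <- numeric(length(starts))
  rms <- numeric(length(starts))
  interp_peak <- function(spec, jj) {
    if (jj > 1 && jj < length(spec)) {
      a <- spec[jj - 1]; b <- spec[jj]; c <- spec[jj + 1]
      denom <- a - 2 * b + c
      dj <- if (abs(denom) > 1e-12) 0.5 * (a - c) / denom else 0
      dj <- max(-0.5, min(0.5, dj))
    } else dj <- 0
    freqs[jj] + dj * fs / nfft
  }
  support <- integer(length(starts))
  specs <- matrix(0, nfft %/% 2, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i] + seq_len(n_frame) - 1]
    rms[i] <- sqrt(mean(seg^2))
    seg <- (seg - mean(seg)) * win
    spec <- Mod(stats::fft(c(seg, numeric(nfft - n_frame))))[seq_len(nfft %/% 2)]
    specs[, i] <- spec
    sb <- spec[band]
    j <- which.max(sb)
    med_mag[i] <- stats::median(sb)
    peak_mag[i] <- sb[j]
    jj <- band[j]
    # octave-error correction: step down to a sufficiently strong
    # subharmonic, repeatedly, until none qualifies; the candidate must
    # be a genuine interior spectral line separated from the parent peak
    # by a valley, so that the parent's window main lobe cannot
    # masquerade as one
    for (iter in 1:3) {
      moved <- FALSE
      for (d in c(3L, 2L)) {
        f_sub <- freqs[jj] / d
        if (f_sub < f_lo) next
        wnd <- which(freqs >= f_sub - 1.5 & freqs <= f_sub + 1.5)
        if (length(wnd) < 3) next
        js <- wnd[which.max(spec[wnd])]
        if (js == wnd[1] || js == wnd[length(wnd)]) next
        if (spec[js] < spec[js - 1] || spec[js] < spec[js + 1]) next
        valley <- min(spec[js:jj])
        if (spec[js] >= subharmonic_ratio * spec[jj] &&
            spec[js] > 4 * med_mag[i] &&
            valley < 0.5 * spec[js]) {
          jj <- js; moved <- TRUE; break
        }
      }
      if (!moved) break
    }
    peak_f[i] <- interp_peak(spec, jj)
    # harmonic support: a true fundamental has spectral lines at its
    # integer multiples and nothing at half-integer multiples, whereas
    # an octave-error candidate (2 x f0) scores lines at both; frames
    # are scored accordingly and the best one anchors the contour
    f_cand <- freqs[jj]
    has_line <- function(fk) {
      if (fk > 0.45 * fs) return(NA)
      wnd <- which(freqs >= fk - 1.5 & freqs <= fk + 1.5)
      if (length(wnd) < 3) return(NA)
      jk <- wnd[which.max(spec[wnd])]
      jk > wnd[1] && jk < wnd[length(wnd)] &&
        spec[jk] >= spec[jk - 1] && spec[jk] >= spec[jk + 1] &&
        spec[jk] > 4 * med_mag[i]
    }
    for (k in 1:5) {
      ok <- has_line(k * f_cand)
      if (isTRUE(ok)) support[i] <- support[i] + 1L
    }
    for (m in c(0.5, 1.5, 2.5)) {
      ok <- has_line(m * f_cand)
      if (isTRUE(ok)) support[i] <- support[i] - 1L
    }
  }
  voiced <- peak_mag > 10^(prominence_db / 20) * pmax(med_mag, 1e-30) &
    rms > 0.1 * stats::median(rms)
  if (!any(voiced)) stop("untraceable call: no voiced frames found")
  # continuity by anchored propagation: start from the most reliable
  # voiced frame and walk outward, limiting jumps to 2 native bins and
  # snapping each frame to its strongest in-window spectral line
  max_jump <- 2 / frame_size
  vi <- which(voiced)
  anchor <- vi[order(-support[vi], -peak_mag[vi])[1]]
  # strongest interior local-max line within max_jump of pred, or NA if
  # the frame holds no resolvable line there (skirts of smeared
  # neighbouring lines rise monotonically and are rejected)
  snap_line <- function(i, pred) {
    spec <- specs[, i]
    wnd <- which(freqs >= max(pred - max_jump, 1) &
                   freqs <= pred + max_jump)
    wnd <- wnd[wnd > 1 & wnd < length(spec)]
    cand <- wnd[spec[wnd] >= spec[wnd - 1] & spec[wnd] >= spec[wnd + 1] &
                  spec[wnd] > 4 * med_mag[i]]
    if (!length(cand)) return(NA_real_)
    interp_peak(spec, cand[which.max(spec[cand])])
  }
  assigned <- peak_f
  run_side <- function(idx) {
    pred <- assigned[anchor]
    for (i in idx) {
      if (!voiced[i]) next
      if (abs(peak_f[i] - pred) > max_jump) {
        s <- snap_line(i, pred)
        if (is.na(s)) {
          # fundamental buried: infer it from the strongest harmonic
          # line, whose harmonic number follows from continuity
          spec <- specs[, i]
          wnd <- band[band > 1 & band < length(spec)]
          cand <- wnd[spec[wnd] >= spec[wnd - 1] & spec[wnd] >= spec[wnd + 1] &
                        spec[wnd] > 4 * med_mag[i]]
          if (length(cand)) {
            fl <- interp_peak(spec, cand[which.max(spec[cand])])
            k <- max(1, round(fl / pred))
            s <- fl / k
          }
        }
        if (is.na(s) || abs(s - pred) > max_jump) {
          voiced[i] <<- FALSE
          assigned[i] <<- pred
        } else assigned[i] <<- s
      }
      pred <- assigned[i]
    }
  }
  if (anchor > 1) run_side(rev(seq_len(anchor - 1)))
  if (anchor < length(starts)) run_side(seq(anchor + 1, length(starts)))
  if (!any(voiced)) stop("untraceable call: no voiced frames found")
  f0_contour(frame_times = (starts - 1 + n_frame / 2) / fs,
             f0 = assigned, frame_size = frame_size, step = step,
             voiced_mask = voiced)
}

#' Extract source-related contour features
#'
#' Computes the standard set of fundamental-frequency descriptors from a
#' traced contour: absolute frequencies (start/mid/finish, min/max, mean,
#' per-third means), temporal locations, and shape measures — coefficient
#' of frequency modulation (sum of absolute successive differences /
#' 10000), jitter factor (100 x mean absolute successive difference
#' relative to the mean frequency), frequency variability index
#' (10 x var(f)/mean(f)^2), and three local slopes read from the contour
#' resampled to 61 equally spaced points (indices 1/20/40/60).
#'
#' @param contour An `f0_contour` with at least 3 voiced frames.
#' @param var_fun Variance convention for the variability index:
#'   `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A one-row data frame of class `source_features` with columns
#'   `start_freq`, `mid_freq`, `finish_freq`, `min_freq`, `max_freq`,
#'   `mean_freq`, `mean_third1..3`, `duration`, `min_freq_loc`,
#'   `max_freq_loc`, `time_min_to_max`, `cofm`, `jitter_factor`,
#'   `freq_variability_index`, `start_slope`, `middle_slope`,
#'   `final_slope`.
#' @export
extract_contour_features <- function(contour, var_fun = c("sample", "population")) {
  stopifnot(inherits(contour, "f0_contour"))
  var_fun <- match.arg(var_fun)
  t <- contour$frame_times[contour$voiced_mask]
  f <- contour$f0[contour$voiced_mask]
  n <- length(f)
  if (n < 3) stop("need at least 3 voiced frames for feature extraction")
  dur <- t[n] - t[1]
  if (dur <= 0) stop("degenerate contour duration")
  mid_idx <- which.min(abs(t - (t[1] + dur / 2)))
  i_min <- which.min(f); i_max <- which.max(f)
  thirds <- findInterval(t, t[1] + dur * c(1, 2) / 3) + 1L  # equal-duration segments
  vf <- stats::var(f)
  if (var_fun == "population") vf <- vf * (n - 1) / n
  mean_f <- mean(f)
  adiff <- sum(abs(diff(f)))
  # slopes on the contour resampled to 61 equally spaced points
  rt <- seq(t[1], t[n], length.out = 61)
  rf <- stats::approx(t, f, xout = rt)$y
  slope <- function(i, j) (rf[j] - rf[i]) / (rt[j] - rt[i])
  out <- data.frame(
    start_freq = f[1], mid_freq = f[mid_idx], finish_freq = f[n],
    min_freq = f[i_min], max_freq = f[i_max], mean_freq = mean_f,
    mean_third1 = mean(f[thirds == 1]),
    mean_third2 = mean(f[thirds == 2]),
    mean_third3 = mean(f[thirds == 3]),
    duration = dur,
    min_freq_loc = t[i_min] - t[1],
    max_freq_loc = t[i_max] - t[1],
    time_min_to_max = abs(t[i_max] - t[i_min]),
    cofm = adiff / 10000,
    jitter_factor = 100 * (adiff / mean_f) / (n - 1),
    freq_variability_index = 10 * vf / mean_f^2,
    start_slope = slope(1, 20), middle_slope = slope(20, 40),
    final_slope = slope(40, 60))
  class(out) <- c("source_features", "data.frame")
  out
}

#' Export a contour as a two-column data frame
#'
#' @param contour An `f0_contour`.
#' @param voiced_only Drop unvoiced frames (default `TRUE`).
#' @return Data frame with columns `time_s`, `f0_hz`.
#' @export
contour_to_table <- function(contour, voiced_only = TRUE) {
  keep <- if (voiced_only) contour$voiced_mask else rep(TRUE, length(contour$f0))
  data.frame(time_s = contour$frame_times[keep], f0_hz = contour$f0[keep])
}
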