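#' Specification of a single synthetic rumble
#'
#' Bundles the source (fundamental frequency contour) and filter (vocal
#' tract resonance) parameters of one synthetic call. The production model
#' follows source-filter theory: a harmonic glottal source whose
#' fundamental sweeps piecewise-linearly from `f0_start` through `f0_mid`
#' to `f0_end`, shaped by an all-pole resonator with one resonance per
#' formant.
#'
#' @param f0_start,f0_mid,f0_end Fundamental frequency (Hz) at the start,
#'   temporal midpoint and end of the call. All must be positive and below
#'   the first formant.
#' @param duration Call duration in seconds (> 0).
#' @param formant_freqs Numeric vector of at least two strictly ascending
#'   formant centre frequencies (Hz), all below 1000 Hz.
#' @param formant_bandwidths Resonance bandwidths (Hz); default 10% of the
#'   centre frequency, which keeps the peaks resolvable at infrasonic
#'   formant spacing.
#' @param harmonic_count Number of source harmonics. The default covers
#'   the spectrum up to roughly 500 Hz.
#' @param noise_snr Signal-to-noise ratio of added Gaussian noise in dB;
#'   `Inf` for a noise-free call.
#' @param sample_rate Output sample rate in Hz; must be at least four
#'   times the highest formant.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `synth_call_spec`.
#' @seealso [synthesize_rumble()]
#' @export
synth_call_spec <- function(f0_start = 10, f0_mid = 14, f0_end = 11,
                            duration = 4,
                            formant_freqs = c(21.5, 77.1),
                            formant_bandwidths = 0.1 * formant_freqs,
                            harmonic_count = max(10L, ceiling(500 / min(f0_start, f0_mid, f0_end))),
                            noise_snr = 40,
                            sample_rate = 4000,
                            seed = 1L) {
  f0 <- c(f0_start, f0_mid, f0_end)
  if (any(!is.finite(f0)) || any(f0 <= 0))
    stop("all f0 values must be positive and finite")
  if (duration <= 0) stop("duration must be positive")
  if (length(formant_freqs) < 2L)
    stop("at least two formant frequencies are required")
  if (any(diff(formant_freqs) <= 0))
    stop("formant_freqs must be strictly ascending")
  if (any(f0 >= formant_freqs[1L]))
    stop("f0 must lie below the first formant")
  if (max(formant_freqs) >= 1000)
    stop("formants must lie below 1000 Hz")
  if (sample_rate < 4 * max(formant_freqs))
    stop("sample_rate must be at least 4 times the highest formant ",
         "(", max(formant_freqs), " Hz)")
  if (length(formant_bandwidths) == 1L)
    formant_bandwidths <- rep(formant_bandwidths, length(formant_freqs))
  stopifnot(length(formant_bandwidths) == length(formant_freqs),
            all(formant_bandwidths > 0))
  structure(list(f0_start = f0_start, f0_mid = f0_mid, f0_end = f0_end,
                 duration = duration,
                 formant_freqs = formant_freqs,
                 formant_bandwidths = formant_bandwidths,
                 harmonic_count = as.integer(harmonic_count),
                 noise_snr = noise_snr,
                 sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "synth_call_spec")
}

#' Synthesize one rumble waveform from a call specification
#'
#' Builds a harmonic source by phase integration of the piecewise-linear
#' fundamental contour, with a -6 dB/octave amplitude rolloff across
#' harmonics, passes it through a cascade of two-pole resonators (one per
#' formant), applies a raised-cosine onset/offset ramp (calls start and
#' end gradually, and an abrupt edge would ring the narrow resonators),
#' adds Gaussian noise at the requested SNR, and peak-normalizes.
#'
#' @param spec A [synth_call_spec()].
#' @param apply_filter Set `FALSE` to skip the formant filter and return
#'   the bare source (useful for source-only fixtures).
#' @param ramp Onset/offset ramp length in seconds (shortened to a tenth
#'   of the duration for very short calls).
#' @return A list of class `rumble_wave` with elements `samples` (numeric
#'   vector, peak-normalized to 0.95), `sample_rate`, and `ground_truth`
#'   (true F0 anchor points, formants and uniform-tube vocal tract length).
#' @examples
#' w <- synthesize_rumble(synth_call_spec(12, 12, 12, duration = 2))
#' length(w$samples) / w$sample_rate
#' @export
synthesize_rumble <- function(spec, apply_filter = TRUE, ramp = 0.15) {
  stopifnot(inherits(spec, "synth_call_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  t <- seq_len(n) / fs
  # piecewise-linear instantaneous F0: start -> mid (at duration/2) -> end
  half <- spec$duration / 2
  f0_t <- ifelse(t <= half,
                 spec$f0_start + (spec$f0_mid - spec$f0_start) * t / half,
                 spec$f0_mid + (spec$f0_end - spec$f0_mid) * (t - half) / half)
  phase <- 2 * pi * cumsum(f0_t) / fs
  k <- seq_len(spec$harmonic_count)
  amp <- 1 / k  # -6 dB/octave source rolloff
  # drop harmonics above 90% of Nyquist to avoid aliasing
  fmax_harm <- max(f0_t) * k
  amp[fmax_harm > 0.45 * fs] <- 0
  src <- as.vector(sin(outer(phase, k)) %*% amp)
  x <- if (apply_filter) {
    y <- src
    for (i in seq_along(spec$formant_freqs)) {
      y <- resonator(y, fs, spec$formant_freqs[i], spec$formant_bandwidths[i])
    }
    y
  } else src
  n_ramp <- round(min(ramp, spec$duration / 10) * fs)
  if (n_ramp > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * r
    x[n - n_ramp + seq_len(n_ramp)] <- x[n - n_ramp + seq_len(n_ramp)] * rev(r)
  }
  if (is.finite(spec$noise_snr)) {
    rms <- sqrt(mean(x^2))
    sigma <- rms / 10^(spec$noise_snr / 20)
    noise <- withr_seed(spec$seed, stats::rnorm(n, 0, sigma))
    x <- x + noise
  }
  x <- 0.95 * x / max(abs(x))
  structure(list(samples = x, sample_rate = fs,
                 ground_truth = list(
                   f0_start = spec$f0_start, f0_mid = spec$f0_mid,
                   f0_end = spec$f0_end,
                   formants = spec$formant_freqs,
                   vtl_m = estimate_vtl(spec$formant_freqs[1L],
                                        spec$formant_freqs[2L]))),
            class = "rumble_wave")
}

# two-pole resonator with unit gain at the centre frequency
resonator <- function(x, fs, f, bw) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * f / fs
  a <- c(1, -2 * r * cos(theta), r^2)
  y <- as.numeric(signal::filter(signal::Arma(b = 1, a = a), x))
  # normalize gain at f
  z <- exp(-1i * theta)
  g <- Mod(1 / (1 + a[2] * z + a[3] * z^2))
  y / g
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stage seed derived from a global seed
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h) %% .Machine$integer.max)
}

#' Specification of a simulated rumble cohort
#'
#' Describes a two-group cohort of individuals whose per-call acoustic
#' features are drawn from group-level Gaussian distributions with
#' additive per-individual random intercepts: feature value =
#' group mean + individual offset + residual, with
#' offset ~ N(0, `individual_effect_sd`) and residual ~ N(0, group SD).
#'
#' @param group_means Matrix or data frame (groups x features) of feature
#'   means; rownames are group labels, colnames feature names.
#' @param group_sds Residual SDs, same shape as `group_means`.
#' @param n_individuals Individuals per group (scalar or per-group vector).
#' @param calls_per_ind Either a length-2 `c(min, max)` range from which
#'   each individual's call count is drawn uniformly, or a list (one
#'   vector per group) of exact per-individual call counts.
#' @param individual_effect_sd Per-feature SD of the individual intercepts,
#'   as a fraction of the residual SD (scalar) or an absolute per-feature
#'   vector with `absolute = TRUE`.
#' @param absolute Interpret `individual_effect_sd` as absolute Hz-scale
#'   SDs rather than a fraction of the residual SD.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @seealso [table3_cohort_spec()] for the reference-calibrated preset.
#' @export
cohort_spec <- function(group_means, group_sds,
                        n_individuals = 5,
                        calls_per_ind = c(10, 20),
                        individual_effect_sd = 0.2,
                        absolute = FALSE,
                        seed = 1L) {
  group_means <- as.matrix(group_means)
  group_sds <- as.matrix(group_sds)
  stopifnot(identical(dim(group_means), dim(group_sds)))
  if (any(group_sds < 0)) stop("SDs must be non-negative")
  if (is.null(rownames(group_means)))
    rownames(group_means) <- rownames(group_sds) <- paste0("group", seq_len(nrow(group_means)))
  if (length(n_individuals) == 1L)
    n_individuals <- rep(n_individuals, nrow(group_means))
  if (any(n_individuals < 1)) stop("need at least one individual per group")
  structure(list(group_means = group_means, group_sds = group_sds,
                 n_individuals = as.integer(n_individuals),
                 calls_per_ind = calls_per_ind,
                 individual_effect_sd = individual_effect_sd,
                 absolute = absolute,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Cohort specification calibrated to the reference male cohort
#'
#' Preset reproducing the study design of the reference dataset: two
#' maturity groups of five males each, the five screened acoustic
#' features (formants 1-2, max/min/finish fundamental frequency) drawn
#' from the published group means and SDs, and per-individual call counts
#' matching the published cohort (group totals 79 and 83 calls).
#'
#' @inheritParams cohort_spec
#' @param calls_per_ind Defaults to the exact published per-individual
#'   call counts; pass a `c(min, max)` range to randomize instead.
#' @return A `cohort_spec`.
#' @export
table3_cohort_spec <- function(individual_effect_sd = 0.2, seed = 1L,
                               calls_per_ind = NULL) {
  ref <- table3_reference()
  m <- rbind(group1 = ref$mean1, group2 = ref$mean2)
  s <- rbind(group1 = ref$sd1, group2 = ref$sd2)
  colnames(m) <- colnames(s) <- ref$feature
  if (is.null(calls_per_ind)) {
    t1 <- table1_subjects()
    t1 <- t1[t1$n_calls >= 10, ]
    calls_per_ind <- split(pmin(t1$n_calls, 20), t1$maturity_group)
  }
  cohort_spec(m, s, n_individuals = 5, calls_per_ind = calls_per_ind,
              individual_effect_sd = individual_effect_sd, seed = seed)
}

#' Draw a feature-level cohort sample
#'
#' For each individual draws one per-feature random intercept, then draws
#' per-call feature values around the shifted group mean. Reproducible:
#' identical spec and seed give byte-identical tables.
#'
#' @param cohort A [cohort_spec()].
#' @return A data frame with columns `call_id`, `individual`,
#'   `maturity_group`, then one column per feature.
#' @export
sample_feature_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  withr_seed(cohort$seed, {
    rows <- list()
    feats <- colnames(cohort$group_means)
    for (g in seq_len(nrow(cohort$group_means))) {
      gname <- rownames(cohort$group_means)[g]
      mu <- cohort$group_means[g, ]
      sdv <- cohort$group_sds[g, ]
      eff_sd <- if (isTRUE(cohort$absolute)) {
        rep_len(cohort$individual_effect_sd, length(mu))
      } else cohort$individual_effect_sd * sdv
      if (is.list(cohort$calls_per_ind)) {
        ncalls <- cohort$calls_per_ind[[g]]
        stopifnot(length(ncalls) == cohort$n_individuals[g])
      } else {
        rng <- cohort$calls_per_ind[1]:cohort$calls_per_ind[2]
        ncalls <- if (length(rng) == 1L) {
          rep(rng, cohort$n_individuals[g])
        } else sample(rng, cohort$n_individuals[g], replace = TRUE)
      }
      for (i in seq_len(cohort$n_individuals[g])) {
        offset <- stats::rnorm(length(mu), 0, eff_sd)
        vals <- sapply(seq_along(mu), function(j)
          stats::rnorm(ncalls[i], mu[j] + offset[j], sdv[j]))
        vals <- matrix(vals, nrow = ncalls[i],
                       dimnames = list(NULL, feats))
        rows[[length(rows) + 1L]] <- data.frame(
          individual = sprintf("%s_ind%d", gname, i),
          maturity_group = gname, vals,
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- cbind(call_id = sprintf("call%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Generate a waveform-level cohort with ground truth
#'
#' Composes [sample_feature_cohort()] with [synthesize_rumble()]: each
#' sampled feature row is mapped to a call spec (F0 rising from the
#' sampled minimum to the maximum then falling to the finish frequency,
#' formants at the sampled F1/F2) and rendered to a 16-bit PCM WAV file.
#' Writes an annotation table and a ground-truth sidecar alongside.
#'
#' @param cohort A [cohort_spec()] whose features include `formant1`,
#'   `formant2`, `max_freq`, `min_freq`, `finish_freq`.
#' @param outdir Output directory (created if absent).
#' @param duration_range Call durations are drawn uniformly from this
#'   range in seconds.
#' @param noise_snr,sample_rate Passed to each call's [synth_call_spec()].
#' @return Invisibly, a list with `annotations` (data frame, one row per
#'   call: `call_id`, `file`, `t_start_s`, `t_end_s`, `individual`,
#'   `maturity_group`) and `ground_truth` (true contour anchors, formants
#'   and VTL per call). Both are also written as CSV into `outdir`.
#' @export
make_waveform_cohort <- function(cohort, outdir,
                                 duration_range = c(3, 6),
                                 noise_snr = 40, sample_rate = 4000) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  feat <- sample_feature_cohort(cohort)
  need <- c("formant1", "formant2", "max_freq", "min_freq", "finish_freq")
  if (!all(need %in% names(feat)))
    stop("cohort features must include: ", paste(need, collapse = ", "))
  durs <- withr_seed(derive_seed(cohort$seed, "durations"),
                     stats::runif(nrow(feat), duration_range[1], duration_range[2]))
  ann <- gt <- vector("list", nrow(feat))
  for (i in seq_len(nrow(feat))) {
    sp <- synth_call_spec(
      f0_start = feat$min_freq[i], f0_mid = feat$max_freq[i],
      f0_end = feat$finish_freq[i], duration = durs[i],
      formant_freqs = c(feat$formant1[i], feat$formant2[i]),
      noise_snr = noise_snr, sample_rate = sample_rate,
      seed = derive_seed(cohort$seed, paste0("call", i)))
    w <- synthesize_rumble(sp)
    f <- file.path(outdir, paste0(feat$call_id[i], ".wav"))
    write_wav(w, f)
    ann[[i]] <- data.frame(call_id = feat$call_id[i], file = basename(f),
                           t_start_s = 0,
                           t_end_s = length(w$samples) / sample_rate,
                           individual = feat$individual[i],
                           maturity_group = feat$maturity_group[i],
                           stringsAsFactors = FALSE)
    gt[[i]] <- data.frame(call_id = feat$call_id[i],
                          f0_start = sp$f0_start, f0_mid = sp$f0_mid,
                          f0_end = sp$f0_end,
                          formant1 = sp$formant_freqs[1],
                          formant2 = sp$formant_freqs[2],
                          vtl_m = w$ground_truth$vtl_m,
                          seed = sp$seed, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, ann)
  gt <- do.call(rbind, gt)
  utils::write.csv(ann, file.path(outdir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(gt, file.path(outdir, "ground_truth.csv"), row.names = FALSE)
  invisible(list(annotations = ann, ground_truth = gt))
}

#' @export
print.rumble_wave <- function(x, ...) {
  cat(sprintf("<rumble_wave: %.2f s at %d Hz>\n",
              length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}
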