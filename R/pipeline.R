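#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end analysis. Each
#' randomized stage derives its own seed deterministically from the
#' global `seed` plus the stage name, so a full run is reproducible from
#' the single integer.
#'
#' @param input Either a `cohort_spec` (features are simulated), a data
#'   frame of per-call features with `individual` and `maturity_group`
#'   columns, or a path to such a CSV.
#' @param min_calls,cap Cohort inclusion rule (see [select_calls()]).
#' @param alpha ANOVA screen threshold.
#' @param pic_correction Small-sample correction in the PIC screen.
#' @param n_selections,n_permutations,n_perm_selections pDFA settings.
#' @param seed Global integer seed.
#' @param outdir Optional directory; when set, reports, feature tables
#'   and the resolved configuration are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, min_calls = 10, cap = 20, alpha = 0.05,
                       pic_correction = TRUE,
                       n_selections = 100, n_permutations = 1000,
                       n_perm_selections = 10, seed = 1L, outdir = NULL) {
  structure(list(input = input, min_calls = min_calls, cap = cap,
                 alpha = alpha, pic_correction = pic_correction,
                 n_selections = n_selections,
                 n_permutations = n_permutations,
                 n_perm_selections = n_perm_selections,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

resolve_features <- function(config) {
  inp <- config$input
  feat <- if (inherits(inp, "cohort_spec")) {
    sample_feature_cohort(inp)
  } else if (is.character(inp)) {
    utils::read.csv(inp, stringsAsFactors = FALSE)
  } else as.data.frame(inp)
  need <- c("individual", "maturity_group")
  if (!all(need %in% names(feat)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  if (!nrow(feat)) stop("empty feature table")
  select_calls(feat, config$min_calls, config$cap,
               seed = derive_seed(config$seed, "select"))
}

feature_columns <- function(feat) {
  drop <- c("call_id", "individual", "maturity_group", "file",
            "t_start_s", "t_end_s")
  feat[setdiff(names(feat), drop)]
}

write_run_outputs <- function(config, report, name) {
  if (is.null(config$outdir)) return(invisible(NULL))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config[setdiff(names(config), c("input", "outdir"))]
  writeLines(paste0(names(cfg), " = ", vapply(cfg, format, character(1))),
             file.path(config$outdir, paste0(name, "_config.txt")))
  slim <- report
  slim$pdfa$perm_distribution <- NULL
  jsonlite::write_json(slim, file.path(config$outdir, paste0(name, "_report.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Full maturity analysis: ANOVA screen, PCA, nested pDFA
#'
#' Tests whether calls can be classified to maturity group. Features are
#' screened by the two-group ANOVA (retain p < alpha), reduced by PCA
#' with Kaiser retention and varimax rotation, and the factor scores are
#' entered into the nested pDFA with maturity group as test factor and
#' individual as control factor.
#'
#' @param config A [run_config()].
#' @return A list of class `maturity_report`: `group_summary` (means, SDs
#'   and F per feature), `screen` (ANOVA table), `factors` (factor
#'   model), `pdfa` (`pdfa_result`), `n_calls` per group.
#' @export
run_maturity_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  feat <- resolve_features(config)
  vals <- feature_columns(feat)
  screen <- anova_screen(vals, feat$maturity_group, alpha = config$alpha)
  kept <- screen$feature[screen$keep]
  if (length(kept) < 2)
    stop("fewer than 2 features survive the ANOVA screen")
  fm <- fit_factors(vals[kept])
  pd <- run_pdfa(fm$scores, test = feat$maturity_group,
                 control = feat$individual,
                 n_selections = config$n_selections,
                 n_permutations = config$n_permutations,
                 n_perm_selections = config$n_perm_selections,
                 seed = derive_seed(config$seed, "pdfa_maturity"))
  report <- structure(list(group_summary = screen[, c("feature", "F", "p",
                                                      "mean1", "sd1",
                                                      "mean2", "sd2")],
                           screen = screen, factors = fm, pdfa = pd,
                           n_calls = table(feat$maturity_group)),
                      class = "maturity_report")
  write_run_outputs(config, list(screen = screen, pdfa = unclass(pd)),
                    "maturity")
  report
}

#' Full individuality analysis: PIC screen, PCA, restricted pDFA
#'
#' Tests whether calls can be classified to individual. Features are
#' screened by the potential of individual coding (retain PIC > 1),
#' reduced by PCA, and the factor scores are entered into the restricted
#' pDFA with individual as test factor and maturity group as restriction
#' factor (permutations happen only within maturity groups).
#'
#' @param config A [run_config()].
#' @return A list of class `individuality_report`: `screen` (PIC table),
#'   `factors`, `pdfa`, `n_calls` per individual.
#' @export
run_individuality_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  feat <- resolve_features(config)
  vals <- feature_columns(feat)
  screen <- pic_screen(vals, feat$individual,
                       small_sample_correction = config$pic_correction)
  kept <- screen$feature[!is.na(screen$keep) & screen$keep]
  if (length(kept) < 2)
    stop("fewer than 2 features survive the PIC screen")
  fm <- fit_factors(vals[kept])
  pd <- run_pdfa(fm$scores, test = feat$individual,
                 restriction = feat$maturity_group,
                 n_selections = config$n_selections,
                 n_permutations = config$n_permutations,
                 n_perm_selections = config$n_perm_selections,
                 seed = derive_seed(config$seed, "pdfa_individuality"))
  report <- structure(list(screen = screen, factors = fm, pdfa = pd,
                           n_calls = table(feat$individual)),
                      class = "individuality_report")
  write_run_outputs(config, list(screen = as.data.frame(screen),
                                 pdfa = unclass(pd)),
                    "individuality")
  report
}

#' Extract per-call features from segmented audio
#'
#' Runs [trace_f0()], [extract_contour_features()] and
#' [estimate_formants()] over every call in an annotation table. Calls
#' whose contour cannot be traced or with fewer than two measurable
#' formants are excluded and reported by ID with the reason.
#'
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param wav_dir Directory containing the WAV files.
#' @param frame_size,step,f_lo,f_hi Passed to [trace_f0()].
#' @param lpc_order Passed to [estimate_formants()].
#' @return Data frame: `call_id`, `individual`, `maturity_group`, the
#'   source features, `formant1`, `formant2`, `dispersion_f1f2`, `vtl_m`.
#'   Attribute `excluded` lists dropped calls and reasons.
#' @export
extract_call_features <- function(annotations, wav_dir,
                                  frame_size = 0.3, step = 0.04,
                                  f_lo = 5, f_hi = 50, lpc_order = 16) {
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(annotations))) {
    id <- annotations$call_id[i]
    w <- read_wav(file.path(wav_dir, annotations$file[i]))
    i0 <- max(1L, round(annotations$t_start_s[i] * w$sample_rate) + 1L)
    i1 <- min(length(w$samples), round(annotations$t_end_s[i] * w$sample_rate))
    seg <- structure(list(samples = w$samples[i0:i1],
                          sample_rate = w$sample_rate),
                     class = "rumble_wave")
    res <- tryCatch({
      src <- extract_contour_features(
        trace_f0(seg, frame_size, step, f_lo, f_hi))
      fo <- estimate_formants(seg, lpc_order = lpc_order)
      cbind(data.frame(call_id = id,
                       individual = annotations$individual[i],
                       maturity_group = annotations$maturity_group[i],
                       stringsAsFactors = FALSE),
            as.data.frame(src),
            data.frame(formant1 = fo$formants[1], formant2 = fo$formants[2],
                       dispersion_f1f2 = fo$dispersion_f1f2,
                       vtl_m = estimate_vtl(fo$formants[1], fo$formants[2])))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message("excluding call ", id, ": ", res)
      excl[[length(excl) + 1L]] <- data.frame(call_id = id, reason = res,
                                              stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no analyzable calls")
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

#' Pearson product-moment correlation
#'
#' Convenience wrapper used for the age-size consistency check of the
#' cohort (male elephants grow throughout life, so age and shoulder
#' height are strongly correlated).
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient r.
#' @export
pearson_r <- function(x, y) stats::cor(x, y, method = "pearson")
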