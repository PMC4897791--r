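#' Apply the cohort inclusion and subsampling rule
#'
#' Drops individuals contributing fewer than `min_calls` calls and
#' subsamples (uniformly, without replacement, seeded) individuals with
#' more than `cap` calls down to `cap`. Idempotent, and never increases
#' any individual's call count.
#'
#' @param annotations Data frame with at least an `individual` column,
#'   one row per call.
#' @param min_calls Minimum calls for an individual to be retained.
#' @param cap Maximum calls kept per individual.
#' @param seed Integer seed for the subsampling.
#' @return The filtered data frame (original row order preserved).
#' @export
select_calls <- function(annotations, min_calls = 10, cap = 20, seed = 1L) {
  stopifnot("individual" %in% names(annotations))
  counts <- table(annotations$individual)
  keep_ind <- names(counts)[counts >= min_calls]
  dropped <- setdiff(names(counts), keep_ind)
  if (length(dropped))
    message("select_calls: dropped ", length(dropped),
            " individual(s) with < ", min_calls, " calls: ",
            paste(dropped, collapse = ", "))
  rows <- withr_seed(derive_seed(seed, "select_calls"), {
    out <- integer(0)
    for (ind in keep_ind) {
      idx <- which(annotations$individual == ind)
      if (length(idx) > cap) idx <- sort(sample(idx, cap))
      out <- c(out, idx)
    }
    sort(out)
  })
  if (!length(rows)) stop("no individuals satisfy the inclusion rule")
  annotations[rows, , drop = FALSE]
}

#' Two-group one-way ANOVA F statistic
#'
#' Classic equal-variance one-way ANOVA for exactly two groups, with
#' df (1, n1 + n2 - 2); identical to the square of the pooled two-sample
#' t statistic.
#'
#' @param values Numeric response.
#' @param groups Group labels (exactly two levels, each with >= 2 values).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
two_group_anova_f <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  ns <- table(groups)
  if (any(ns < 2)) stop("each group needs at least 2 values")
  sp <- split(values, groups)
  m <- vapply(sp, mean, numeric(1))
  v <- vapply(sp, stats::var, numeric(1))
  n1 <- ns[1]; n2 <- ns[2]
  df2 <- n1 + n2 - 2
  pooled <- ((n1 - 1) * v[1] + (n2 - 1) * v[2]) / df2
  Fst <- if (pooled == 0) {
    if (m[1] == m[2]) 0 else Inf
  } else (m[1] - m[2])^2 / (pooled * (1 / n1 + 1 / n2))
  list(F = unname(Fst), df1 = 1L, df2 = as.integer(df2),
       p = unname(stats::pf(Fst, 1, df2, lower.tail = FALSE)))
}

#' Two-group ANOVA F from published summary moments
#'
#' Reconstructs the pooled one-way F statistic from group means, SDs and
#' sizes alone, for checking published F values against published
#' descriptive tables.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_f_from_moments <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df2 <- n1 + n2 - 2
  pooled <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df2
  Fst <- (mean1 - mean2)^2 / (pooled * (1 / n1 + 1 / n2))
  list(F = Fst, df1 = 1L, df2 = as.integer(df2),
       p = stats::pf(Fst, 1, df2, lower.tail = FALSE))
}

#' ANOVA screen of features between two maturity groups
#'
#' Runs [two_group_anova_f()] per feature and flags features whose group
#' means differ at `alpha` for entry into the subsequent PCA. Excluded
#' features are reported by name.
#'
#' @param features Data frame of numeric feature columns, one row per call.
#' @param groups Two-level group labels, one per row.
#' @param alpha Retention threshold on the two-sided p value.
#' @return Data frame with one row per feature: `feature`, `F`, `df1`,
#'   `df2`, `p`, group `mean1`/`sd1`/`mean2`/`sd2`, and `keep`.
#' @export
anova_screen <- function(features, groups, alpha = 0.05) {
  stopifnot(is.data.frame(features))
  groups <- factor(groups)
  res <- lapply(names(features), function(f) {
    a <- two_group_anova_f(features[[f]], groups)
    sp <- split(features[[f]], groups)
    data.frame(feature = f, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               mean1 = mean(sp[[1]]), sd1 = stats::sd(sp[[1]]),
               mean2 = mean(sp[[2]]), sd2 = stats::sd(sp[[2]]),
               keep = a$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  excl <- out$feature[!out$keep]
  if (length(excl))
    message("anova_screen: excluded (no group difference at alpha = ",
            alpha, "): ", paste(excl, collapse = ", "))
  out
}

#' Potential-of-individual-coding (PIC) screen
#'
#' For each feature computes the within-individual coefficient of
#' variation per individual, CVw = 100 * (1 + 1/(4n)) * SD/mean (the
#' small-sample-corrected CV; the correction can be switched off), the
#' between-individual CV over the pooled sample, CVb = 100 * SD/mean,
#' and their ratio PIC = CVb / mean(CVw). Features with PIC > 1 have the
#' potential to encode individual identity and are flagged for retention.
#'
#' @param features Data frame of numeric feature columns, one row per call.
#' @param individual Individual labels, one per row; >= 2 individuals with
#'   >= 2 calls each.
#' @param small_sample_correction Apply the (1 + 1/(4n)) factor to CVw.
#' @return Data frame of class `pic_table`: `feature`, `mean_cv_within`,
#'   `cv_between`, `pic`, `keep` (PIC > 1), plus attribute `cv_within`
#'   (matrix of per-individual CVw). Features whose pooled mean is zero
#'   are flagged non-computable (`pic = NA`); a zero mean within-CV gives
#'   `pic = Inf` with a warning.
#' @export
pic_screen <- function(features, individual, small_sample_correction = TRUE) {
  stopifnot(is.data.frame(features))
  individual <- factor(individual)
  if (nlevels(individual) < 2) stop("need at least 2 individuals")
  ns <- table(individual)
  if (any(ns < 2)) stop("every individual needs at least 2 calls")
  cvw_mat <- matrix(NA_real_, nlevels(individual), ncol(features),
                    dimnames = list(levels(individual), names(features)))
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    cvw <- vapply(levels(individual), function(ind) {
      xi <- x[individual == ind]
      m <- mean(xi)
      if (m == 0) return(NA_real_)
      corr <- if (small_sample_correction) 1 + 1 / (4 * length(xi)) else 1
      100 * corr * stats::sd(xi) / abs(m)
    }, numeric(1))
    cvw_mat[, f] <<- cvw
    pooled_mean <- mean(x)
    if (pooled_mean == 0 || anyNA(cvw)) {
      return(data.frame(feature = f, mean_cv_within = NA_real_,
                        cv_between = NA_real_, pic = NA_real_,
                        keep = NA, stringsAsFactors = FALSE))
    }
    cvb <- 100 * stats::sd(x) / abs(pooled_mean)
    mcvw <- mean(cvw)
    pic <- if (mcvw == 0) {
      warning("PIC undefined for '", f,
              "': zero within-individual variation; reporting Inf")
      Inf
    } else cvb / mcvw
    data.frame(feature = f, mean_cv_within = mcvw, cv_between = cvb,
               pic = pic, keep = pic > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  excl <- out$feature[!is.na(out$keep) & !out$keep]
  if (length(excl))
    message("pic_screen: excluded (PIC <= 1): ",
            paste(excl, collapse = ", "))
  attr(out, "cv_within") <- cvw_mat
  class(out) <- c("pic_table", "data.frame")
  out
}
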