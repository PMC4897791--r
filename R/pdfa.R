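#' Fit a linear discriminant classifier
#'
#' Fisher/Gaussian linear discriminant analysis with a pooled
#' within-class covariance matrix and equal priors: class c scores
#' x' S^-1 m_c - m_c' S^-1 m_c / 2 and classification is by maximum
#' score. If the pooled covariance is (near-)singular a small ridge is
#' added to its diagonal, with a warning.
#'
#' @param x Numeric matrix or data frame of predictors (training rows).
#' @param y Class labels (>= 2 classes present).
#' @param ridge Ridge added relative to the mean diagonal when the pooled
#'   covariance cannot be inverted.
#' @return A list of class `lda_model` with `means` (classes x features),
#'   `cov_inv`, `classes`.
#' @export
lda_fit <- function(x, y, ridge = 1e-8) {
  X <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("need at least 2 classes in training data")
  if (any(!is.finite(X))) stop("predictors must be finite")
  classes <- levels(y)
  p <- ncol(X)
  M <- matrix(0, length(classes), p,
              dimnames = list(classes, colnames(X)))
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    M[cl, ] <- colMeans(Xc)
    if (nrow(Xc) > 1) {
      D <- sweep(Xc, 2, M[cl, ])
      Sw <- Sw + crossprod(D)
    }
  }
  Sw <- Sw / max(nrow(X) - length(classes), 1L)
  inv <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    warning("pooled covariance singular; adding ridge ", ridge)
    inv <- solve(Sw + diag(ridge * mean(diag(Sw)) + 1e-12, p))
  }
  structure(list(means = M, cov_inv = inv, classes = classes),
            class = "lda_model")
}

#' Classify rows with a fitted linear discriminant model
#'
#' @param model An `lda_model` from [lda_fit()].
#' @param x Matrix or data frame of rows to classify.
#' @return Character vector of predicted class labels.
#' @export
lda_classify <- function(model, x) {
  X <- as.matrix(x)
  A <- model$cov_inv %*% t(model$means)          # p x K
  const <- -0.5 * colSums(t(model$means) * A)    # K
  scores <- sweep(X %*% A, 2, const, `+`)
  model$classes[max.col(scores, ties.method = "first")]
}

#' Chance-normalized classification gain
#'
#' Error reduction re-expresses a percent-correct against its expected
#' chance level: 100 * (observed - expected) / (100 - expected), i.e. the
#' share of the chance error rate that the classifier removed.
#'
#' @param observed_pct,expected_pct Percentages in \[0, 100\],
#'   `expected_pct < 100`.
#' @return Error reduction in percent.
#' @examples
#' error_reduction(98, 200 / 3)  # 94
#' @export
error_reduction <- function(observed_pct, expected_pct) {
  if (any(expected_pct >= 100)) stop("expected_pct must be below 100")
  100 * (observed_pct - expected_pct) / (100 - expected_pct)
}

#' Permuted discriminant function analysis
#'
#' Randomization DFA for non-independent (repeated-calls) designs, in two
#' variants. In the *nested* design (e.g. test factor = maturity group,
#' control factor = individual) each control level belongs to exactly one
#' test level; significance is assessed by reassigning whole control
#' levels across test levels, preserving group sizes, so that the
#' individual — not the call — is the unit of permutation. In the
#' *restricted* design (test factor = individual, restriction factor =
#' maturity group) test-factor labels are shuffled across calls within
#' each restriction level.
#'
#' Each evaluation draws a balanced training set — an equal number of
#' calls per control level (nested) or per test level (restricted), the
#' per-level count being the minimum available (at least 2) — fits the
#' discriminant functions on it, and records the percent correct among
#' the training calls ("original") and among the held-out calls
#' ("cross-validated"). Both are averaged over `n_selections` random
#' selections. Each of the `n_permutations` permutations is evaluated the
#' same way with `n_perm_selections` inner selections, and the p value is
#' the proportion of permutations whose cross-validated statistic reaches
#' the observed one, counting the observed data as one permutation. In
#' the nested design, a drawn permutation that merely reproduces the
#' observed partition of control levels (identically or with class
#' labels exchanged) carries no information about the null and is
#' redrawn.
#'
#' @param features Numeric matrix or data frame of predictor variables
#'   (typically factor scores), one row per call.
#' @param test Test-factor labels per call (what is being discriminated).
#' @param control Control-factor labels (nested design); each level must
#'   map to a single test level. Exactly one of `control`/`restriction`
#'   must be given.
#' @param restriction Restriction-factor labels (restricted design); each
#'   test level must map to a single restriction level.
#' @param n_selections Random balanced selections for the observed data.
#' @param n_permutations Label permutations for the null distribution.
#' @param n_perm_selections Inner selections per permutation (the
#'   permutation mean is what matters, so fewer suffice; raise to
#'   `n_selections` for full fidelity).
#' @param seed Integer seed; the full result is reproducible given it.
#' @return A list of class `pdfa_result`: `pct_correct_original`,
#'   `pct_correct_crossval`, `perm_distribution` (cross-validated % per
#'   permutation), `p_value`, `expected_chance_pct` (mean permuted
#'   cross-validated %), `error_reduction_pct`, `design`, `n_selections`,
#'   `n_permutations`.
#' @export
run_pdfa <- function(features, test, control = NULL, restriction = NULL,
                     n_selections = 100, n_permutations = 1000,
                     n_perm_selections = 10, seed = 1L) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("features must be finite")
  test <- as.character(test)
  stopifnot(length(test) == nrow(X), n_permutations >= 1)
  nested <- !is.null(control)
  if (nested == !is.null(restriction))
    stop("give exactly one of 'control' (nested) or 'restriction' (restricted)")

  if (nested) {
    control <- as.character(control)
    stopifnot(length(control) == nrow(X))
    map <- tapply(test, control, function(v) length(unique(v)))
    if (any(map != 1))
      stop("nested design violated: control level(s) span several test levels: ",
           paste(names(map)[map != 1], collapse = ", "))
    ctl_test <- tapply(test, control, `[`, 1)  # control level -> test level
    if (length(ctl_test) <= length(unique(test)))
      stop("need more control levels than test levels")
    if (min(table(ctl_test)) < 2)
      stop("permutation impossible: a test level has a single control level")
    unit <- control
  } else {
    restriction <- as.character(restriction)
    stopifnot(length(restriction) == nrow(X))
    map <- tapply(restriction, test, function(v) length(unique(v)))
    if (any(map != 1))
      stop("restricted design violated: test level(s) span several restriction levels: ",
           paste(names(map)[map != 1], collapse = ", "))
    unit <- test
  }
  unit_counts <- table(unit)
  if (min(unit_counts) < 2)
    stop("every ", if (nested) "control" else "test",
         " level needs at least 2 calls")
  n_per <- min(unit_counts)
  # keep at least one held-out call overall so the cross-validated
  # statistic exists even in perfectly balanced designs
  if (all(unit_counts == n_per)) n_per <- n_per - 1L
  if (n_per < 2L)
    stop("too few calls per level for balanced cross-validation")

  # one balanced selection: returns c(original %, crossval %)
  eval_once <- function(test_labels) {
    train <- integer(0)
    for (lv in unique(unit)) {
      idx <- which(unit == lv)
      train <- c(train, if (length(idx) > n_per) sample(idx, n_per) else idx)
    }
    heldout <- setdiff(seq_len(nrow(X)), train)
    fit <- lda_fit(X[train, , drop = FALSE], test_labels[train])
    orig <- 100 * mean(lda_classify(fit, X[train, , drop = FALSE]) ==
                         test_labels[train])
    cv <- if (length(heldout)) {
      100 * mean(lda_classify(fit, X[heldout, , drop = FALSE]) ==
                   test_labels[heldout])
    } else NA_real_
    c(orig, cv)
  }
  eval_mean <- function(test_labels, reps) {
    rowMeans(vapply(seq_len(reps), function(i) eval_once(test_labels),
                    numeric(2)), na.rm = TRUE)
  }
  # signature of a grouping of control levels, invariant to class labels,
  # used to reject permutations that merely reproduce the observed split
  partition_sig <- function(assign, lv) {
    paste(sort(vapply(split(lv, assign), function(s)
      paste(sort(s), collapse = ","), character(1))), collapse = "|")
  }
  permute_labels <- function() {
    if (nested) {
      lv <- names(ctl_test)
      orig_sig <- partition_sig(as.character(ctl_test), lv)
      for (try in 1:100) {
        new_assign <- stats::setNames(sample(as.character(ctl_test)), lv)
        if (partition_sig(as.character(new_assign), lv) != orig_sig) break
      }
      unname(new_assign[control])
    } else {
      out <- test
      for (r in unique(restriction)) {
        idx <- which(restriction == r)
        out[idx] <- test[sample(idx)]
      }
      out
    }
  }

  withr_seed(derive_seed(seed, "pdfa"), {
    obs <- eval_mean(test, n_selections)
    perm_cv <- vapply(seq_len(n_permutations), function(b) {
      eval_mean(permute_labels(), n_perm_selections)[2]
    }, numeric(1))
    p <- (sum(perm_cv >= obs[2]) + 1) / (n_permutations + 1)
    expected <- mean(perm_cv)
    structure(list(
      pct_correct_original = obs[1],
      pct_correct_crossval = obs[2],
      perm_distribution = perm_cv,
      p_value = p,
      expected_chance_pct = expected,
      error_reduction_pct = error_reduction(obs[2], expected),
      design = if (nested) "nested" else "restricted",
      n_selections = n_selections,
      n_permutations = n_permutations), class = "pdfa_result")
  })
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf(paste0(
    "pDFA (%s design, %d selections, %d permutations)\n",
    "  correct, original data:      %.1f%%\n",
    "  correct, cross-validated:    %.1f%%\n",
    "  expected chance level:       %.1f%%\n",
    "  error reduction:             %.1f%%\n",
    "  p value:                     %.4g\n"),
    x$design, x$n_selections, x$n_permutations,
    x$pct_correct_original, x$pct_correct_crossval,
    x$expected_chance_pct, x$error_reduction_pct, x$p_value))
  invisible(x)
}
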