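#' Principal-component factor model with varimax rotation
#'
#' Standard variable-reduction recipe: z-standardize the features,
#' eigendecompose their correlation matrix, retain components with
#' eigenvalues above 1.0 (Kaiser criterion), varimax-rotate the retained
#' loadings (Kaiser-normalized), and form regression-method factor score
#' coefficients, W = R^-1 L, so that scores = Z W. Each factor's sign is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param features Data frame or matrix of numeric features (rows are
#'   calls); needs more rows than features.
#' @param kaiser_threshold Eigenvalue cutoff for retention (default 1.0).
#' @return A list of class `factor_model`: `center`/`scale` (per-feature
#'   standardization), `eigenvalues` (all), `n_retained`, `loadings`
#'   (features x factors, rotated), `rotmat`, `score_coef`,
#'   `variance_explained_pct`, and `scores` for the training rows.
#' @export
fit_factors <- function(features, kaiser_threshold = 1.0) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("features must be numeric")
  p <- ncol(X)
  if (p < 2) stop("need at least 2 features")
  if (nrow(X) <= p) stop("need more rows than features")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant feature(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Z <- scale(X, ctr, scl)
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    cc <- which(abs(R) > 1 - 1e-8 & row(R) < col(R), arr.ind = TRUE)
    pairs <- if (nrow(cc)) paste(rownames(R)[cc[, 1]], colnames(R)[cc[, 2]],
                                 sep = " ~ ", collapse = ", ") else "(unidentified)"
    stop("singular correlation matrix; collinear features: ", pairs)
  }
  k <- sum(ev$values > kaiser_threshold)
  if (k < 1) k <- 1L
  L <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(k)]), k)
  rownames(L) <- colnames(X)
  if (k > 1) {
    vm <- stats::varimax(L, normalize = TRUE)
    L <- unclass(vm$loadings)
    rot <- vm$rotmat
  } else rot <- diag(1)
  # sign convention: largest-magnitude loading positive per factor
  sgn <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, `*`)
  rot <- sweep(rot, 2, sgn, `*`)
  colnames(L) <- paste0("factor", seq_len(k))
  W <- solve(R, L)
  scores <- Z %*% W
  colnames(scores) <- colnames(L)
  structure(list(center = ctr, scale = scl, eigenvalues = ev$values,
                 n_retained = k, loadings = L, rotmat = rot,
                 score_coef = W,
                 variance_explained_pct = 100 * sum(ev$values[seq_len(k)]) / p,
                 scores = scores),
            class = "factor_model")
}

#' Factor scores for new observations
#'
#' Applies a fitted [fit_factors()] model to new rows: standardize with
#' the training means/SDs, then multiply by the regression-method score
#' coefficients. Training-data scores have mean ~ 0 by construction.
#'
#' @param model A `factor_model`.
#' @param newdata Data frame or matrix with the model's feature columns.
#' @return Matrix of factor scores (rows x retained factors).
#' @export
score_factors <- function(model, newdata) {
  stopifnot(inherits(model, "factor_model"))
  X <- as.matrix(newdata)[, names(model$center), drop = FALSE]
  Z <- scale(X, model$center, model$scale)
  S <- Z %*% model$score_coef
  colnames(S) <- colnames(model$loadings)
  S
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d of %d components retained (eigenvalue > 1), %.1f%% variance\n",
              x$n_retained, length(x$eigenvalues), x$variance_explained_pct))
  print(round(x$loadings, 3))
  invisible(x)
}
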