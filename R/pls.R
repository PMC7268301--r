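#' Fit a PLS1 regression model by NIPALS
#'
#' Univariate-response partial least squares on column-centered `X` and
#' centered `y`.  Per component: weight `w` proportional to `X'y`,
#' normalized to unit length; scores `t = X w`; loadings
#' `p = X't / (t't)`, `q = y't / (t't)`; then `X` and `y` are deflated.
#' The regression vector is assembled as `b = W (P'W)^-1 q`, so that
#' predictions are `(X_new - x_mean) b + y_mean`.  Columns are centered
#' but not variance-scaled (standard for spectra, where variance carries
#' signal).
#'
#' If the residual matrix is exhausted before `n_lv` components (rank
#' deficiency), fitting stops early with a warning and the achieved
#' number of components is recorded in the model.
#'
#' @param X numeric matrix, `n x p`.
#' @param y numeric response vector of length `n` with nonzero variance.
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param wavenumbers optional numeric axis stored with the model (used
#'   by [smc()] and selection bookkeeping).
#' @return An object of class `pls1_model`: list with `n_lv`, `x_mean`,
#'   `y_mean`, `weights` (p x a), `x_loadings` (p x a), `y_loadings`
#'   (length a), `scores` (n x a, mutually orthogonal), `rotation`
#'   (`W (P'W)^-1`), `coef` (regression vector at `n_lv`), `coef_path`
#'   (p x a matrix of regression vectors for 1..a components) and
#'   `wavenumbers`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X[, 1] + rnorm(10, sd = 0.1)
#' m <- fit_pls1(X, y, 2)
#' cor(predict(m, X), y)
fit_pls1 <- function(X, y, n_lv, wavenumbers = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) {
    stop_nirdecon("length(y) must equal nrow(X)", "nirdecon_shape_error")
  }
  if (var(y) == 0) {
    stop_nirdecon("zero-variance response: PLS1 undefined",
                  "nirdecon_degenerate_error")
  }
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    stop_nirdecon(sprintf(
      "n_lv must be in [1, %d] (min(n - 1, p)); got %d",
      min(n - 1, p), n_lv), "nirdecon_config_error")
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xd <- X - rep(x_mean, each = n)
  yd <- y - y_mean
  x_scale <- sum(Xd^2)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  a <- 0L
  for (k in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn^2 <= 1e-14 * x_scale * sum(yd^2) || wn == 0) break
    w <- w / wn
    t <- as.numeric(Xd %*% w)
    tt <- sum(t^2)
    if (tt <= 1e-14 * x_scale) break
    pk <- as.numeric(crossprod(Xd, t)) / tt
    qk <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pk)
    yd <- yd - qk * t
    W[, k] <- w
    P[, k] <- pk
    Tm[, k] <- t
    q[k] <- qk
    a <- k
  }
  if (a == 0L) {
    # y carries no covariance with X: the only defensible fit is the
    # zero regression vector, predicting the training mean everywhere
    warning("X carries no covariance with y; returning zero-coefficient model")
    return(structure(list(
      n_lv = 1L, x_mean = x_mean, y_mean = y_mean,
      weights = matrix(0, p, 1), x_loadings = matrix(0, p, 1),
      y_loadings = 0, scores = matrix(0, n, 1),
      rotation = matrix(0, p, 1), coef = numeric(p),
      coef_path = matrix(0, p, 1), wavenumbers = wavenumbers
    ), class = "pls1_model"))
  }
  if (a < n_lv) {
    warning(sprintf(
      "rank exhausted after %d of %d requested components", a, n_lv))
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    Tm <- Tm[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
  }
  # regression vectors for every component count 1..a
  coef_path <- matrix(0, p, a)
  PtW <- crossprod(P, W)  # upper triangular for NIPALS
  for (k in seq_len(a)) {
    coef_path[, k] <- W[, seq_len(k), drop = FALSE] %*%
      solve(PtW[seq_len(k), seq_len(k), drop = FALSE], q[seq_len(k)])
  }
  rotation <- W %*% solve(PtW)
  structure(list(
    n_lv = a, x_mean = x_mean, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = q, scores = Tm,
    rotation = rotation, coef = coef_path[, a],
    coef_path = coef_path, wavenumbers = wavenumbers
  ), class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("pls1_model: %d latent variables, %d variables\n",
              x$n_lv, length(x$coef)))
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' @param object a [fit_pls1()] model.
#' @param newdata numeric matrix (or single-spectrum vector) with the
#'   training number of columns, or a [spectra_set()].
#' @param n_lv number of components to use (default: all fitted).
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
predict.pls1_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$absorbance
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop_nirdecon(sprintf(
      "newdata has %d columns; model was trained on %d",
      ncol(newdata), length(object$x_mean)), "nirdecon_shape_error")
  }
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > object$n_lv) {
    stop_nirdecon(sprintf("n_lv must be in [1, %d]", object$n_lv),
                  "nirdecon_config_error")
  }
  Xc <- newdata - rep(object$x_mean, each = nrow(newdata))
  as.numeric(Xc %*% object$coef_path[, n_lv]) + object$y_mean
}

#' Scores of (new) observations in a PLS1 model
#'
#' Projects centered spectra onto the model's score space via the
#' rotation `W (P'W)^-1`; on the training data this reproduces the
#' NIPALS scores.
#'
#' @param m a [fit_pls1()] model.
#' @param X numeric matrix or [spectra_set()].
#' @return Numeric matrix `n x n_lv` of scores.
#' @export
pls_scores <- function(m, X) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  if (ncol(X) != length(m$x_mean)) {
    stop_nirdecon("column count does not match the model",
                  "nirdecon_shape_error")
  }
  (X - rep(m$x_mean, each = nrow(X))) %*% m$rotation
}

#' Leave-one-out cross-validation for PLS1
#'
#' For each left-out sample the model is refit on the remaining `n - 1`
#' samples (re-centering inside the loop) and the sample is predicted
#' with every candidate component count.  The chosen component count is
#' the smallest one whose RMSECV is within 2 percent of the global
#' minimum (parsimony rule).
#'
#' @param X numeric matrix, `n x p`, `n >= 3`.
#' @param y numeric response of length `n`.
#' @param max_lv maximum candidate component count; clipped to
#'   `min(n - 2, p)` with a warning if larger.
#' @return An object of class `pls_cv`: list with `rmsecv_per_lv`,
#'   `chosen_lv`, `cv_predictions` (left-out predictions at the chosen
#'   count) and `cv_pred_matrix` (`n x max_lv`).
#' @export
loo_cv <- function(X, y, max_lv = 20) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) {
    stop_nirdecon("leave-one-out CV needs n >= 3", "nirdecon_config_error")
  }
  max_lv <- as.integer(max_lv)
  lv_cap <- min(n - 2L, ncol(X))
  if (max_lv > lv_cap) {
    warning(sprintf("max_lv clipped from %d to %d (min(n - 2, p))",
                    max_lv, lv_cap))
    max_lv <- lv_cap
  }
  if (max_lv < 1) {
    stop_nirdecon("max_lv must be at least 1", "nirdecon_config_error")
  }
  preds <- matrix(NA_real_, n, max_lv)
  early <- FALSE
  for (i in seq_len(n)) {
    m <- withCallingHandlers(
      fit_pls1(X[-i, , drop = FALSE], y[-i], max_lv),
      warning = function(w) {
        early <<- TRUE
        invokeRestart("muffleWarning")
      })
    for (a in seq_len(max_lv)) {
      preds[i, a] <- predict(m, X[i, , drop = FALSE],
                             n_lv = min(a, m$n_lv))
    }
  }
  if (early) {
    warning("rank exhausted in at least one CV fold; ",
            "higher component counts reuse the largest attainable fit")
  }
  rmsecv <- sqrt(colMeans((y - preds)^2))
  chosen <- min(which(rmsecv <= 1.02 * min(rmsecv)))
  structure(list(rmsecv_per_lv = rmsecv, chosen_lv = chosen,
                 cv_predictions = preds[, chosen],
                 cv_pred_matrix = preds),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("pls_cv: chosen %d of %d components (RMSECV %.4g)\n",
              x$chosen_lv, length(x$rmsecv_per_lv),
              x$rmsecv_per_lv[x$chosen_lv]))
  invisible(x)
}

#' Coefficient of determination and root-mean-square error
#'
#' `rmse = sqrt(mean((y - y_hat)^2))`; `r2 = 1 - SS_res / SS_tot` with
#' `SS_tot` about the mean of `y`.
#'
#' @param y observed values (length >= 2, nonzero variance).
#' @param y_hat predictions of the same length.
#' @return An object of class `fit_metrics`: list with `r2` and `rmse`.
#' @export
fit_metrics <- function(y, y_hat) {
  y <- as.numeric(y)
  y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat) || length(y) < 2) {
    stop_nirdecon("y and y_hat must have equal length >= 2",
                  "nirdecon_shape_error")
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop_nirdecon("zero-variance y: r2 undefined",
                  "nirdecon_degenerate_error")
  }
  ss_res <- sum((y - y_hat)^2)
  structure(list(r2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(mean((y - y_hat)^2))),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("r2 = %.4f, rmse = %.4g\n", x$r2, x$rmse))
  invisible(x)
}
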