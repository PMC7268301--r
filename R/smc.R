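#' Significance multivariate correlation (sMC) profile
#'
#' Per-wavenumber importance of a fitted PLS1 model.  Each row of the
#' centered data matrix is projected onto the direction of the regression
#' vector `b`: with `y_hat = X_c b`, the projected part is
#' `X_hat = y_hat b' / (b'b)` and the residual `E = X_c - X_hat`.  For
#' variable `j`, `SSR_j = sum_i X_hat[i, j]^2` and
#' `SSE_j = sum_i E[i, j]^2`, and the sMC statistic is
#' `F_j = (SSR_j / 1) / (SSE_j / (n - 2))`, referred to the F(1, n - 2)
#' distribution.  A variable is flagged significant when `F_j` exceeds
#' the upper 1 - alpha quantile.
#'
#' The F(1, n - 2) reference is the statistic's conventional calibration;
#' it is approximate, since the regression vector is itself estimated
#' from the same data (see the package vignette for a measured
#' false-positive analysis).
#'
#' @param X training data matrix the model was fitted on (`n x p`,
#'   `n >= 3`).
#' @param y training response (used for dimension checks only; the
#'   statistic depends on `X` and the model).
#' @param m a [fit_pls1()] model fitted on `(X, y)`.
#' @param alpha significance level (default 0.05).
#' @return An object of class `smc_profile`: list with `f_stat` (length
#'   p, nonnegative), `df = c(1, n - 2)`, `alpha`, `f_crit`,
#'   `significant` (logical) and `wavenumbers`.
#' @export
smc <- function(X, y, m, alpha = 0.05) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) stop_nirdecon("sMC needs n >= 3", "nirdecon_config_error")
  if (!is.null(y) && length(y) != n) {
    stop_nirdecon("length(y) must equal nrow(X)", "nirdecon_shape_error")
  }
  if (p != length(m$x_mean)) {
    stop_nirdecon("X column count does not match the model",
                  "nirdecon_shape_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop_nirdecon("alpha must be in (0, 1)", "nirdecon_config_error")
  }
  b <- m$coef
  bb <- sum(b^2)
  if (bb == 0) {
    stop_nirdecon("degenerate model: regression vector is all zeros",
                  "nirdecon_degenerate_error")
  }
  Xc <- X - rep(m$x_mean, each = n)
  y_hat <- as.numeric(Xc %*% b)
  ssy <- sum(y_hat^2)
  ssr <- (b^2 / bb^2) * ssy
  sse <- colSums(Xc^2) - 2 * b * as.numeric(crossprod(Xc, y_hat)) / bb + ssr
  sse <- pmax(sse, 0)  # guard tiny negative round-off
  f_stat <- ssr / (sse / (n - 2))
  f_crit <- qf(1 - alpha, 1, n - 2)
  structure(list(
    f_stat = f_stat, df = c(1, n - 2), alpha = alpha, f_crit = f_crit,
    significant = f_stat > f_crit,
    wavenumbers = m$wavenumbers %||% seq_len(p)
  ), class = "smc_profile")
}

#' @export
print.smc_profile <- function(x, ...) {
  cat(sprintf(
    "smc_profile: %d variables, %d significant at alpha = %g (F crit %.3f)\n",
    length(x$f_stat), sum(x$significant), x$alpha, x$f_crit))
  invisible(x)
}

#' Select trait-specific, confounder-free wavenumbers
#'
#' Applies the dual-response rule: keep wavenumbers significant in the
#' trait profile and not significant in the confounder profile.  With
#' `top_k`, only the `top_k` surviving wavenumbers with the largest trait
#' F statistics are kept (ties broken toward the lower index); the result
#' is always ordered by position on the axis.
#'
#' @param trait [smc()] profile for the trait response.
#' @param confounder [smc()] profile for the confounder response, on the
#'   same wavenumber axis.
#' @param top_k optional cap on the number of selected wavenumbers.
#' @return An object of class `deconfound_selection`: list with
#'   `selected` (axis indices), `wavenumbers`, `n_selected`,
#'   `trait_profile`, `confounder_profile` and `rule`.
#' @export
select_deconfounded <- function(trait, confounder, top_k = NULL) {
  stopifnot(inherits(trait, "smc_profile"),
            inherits(confounder, "smc_profile"))
  if (length(trait$f_stat) != length(confounder$f_stat) ||
      !isTRUE(all.equal(as.numeric(trait$wavenumbers),
                        as.numeric(confounder$wavenumbers)))) {
    stop_nirdecon("trait and confounder profiles are on different axes",
                  "nirdecon_shape_error")
  }
  sel <- which(trait$significant & !confounder$significant)
  rule <- sprintf(
    "trait significant (alpha = %g) and confounder not significant (alpha = %g)",
    trait$alpha, confounder$alpha)
  if (!is.null(top_k) && length(sel) > top_k) {
    ord <- sel[order(-trait$f_stat[sel], sel)]
    sel <- sort(ord[seq_len(top_k)])
    rule <- paste0(rule, sprintf("; top %d by trait F", top_k))
  }
  if (length(sel) == 0) {
    stop_nirdecon(paste0(
      "empty selection: no wavenumber is trait-significant and ",
      "confounder-nonsignificant; consider adjusting alpha"),
      "nirdecon_empty_selection")
  }
  structure(list(
    selected = sel, wavenumbers = trait$wavenumbers[sel],
    n_selected = length(sel), trait_profile = trait,
    confounder_profile = confounder, rule = rule
  ), class = "deconfound_selection")
}

#' @export
print.deconfound_selection <- function(x, ...) {
  cat(sprintf("deconfound_selection: %d of %d wavenumbers (%s)\n",
              x$n_selected, length(x$trait_profile$f_stat), x$rule))
  invisible(x)
}

#' Refit a PLS1 model on the selected wavenumbers
#'
#' Restricts the (pre-processed) spectra to the selected columns, then
#' runs [loo_cv()] to choose the component count and [fit_pls1()] at the
#' chosen count.
#'
#' @param s a [spectra_set()] on the axis the selection was made on.
#' @param sel a [select_deconfounded()] selection.
#' @param response name of the metadata column to predict (`"ec"` or
#'   `"angle"`).
#' @param max_lv maximum candidate component count for the CV.
#' @return List with elements `model` ([fit_pls1()]) and `cv`
#'   ([loo_cv()]).
#' @export
refit_on_selection <- function(s, sel, response, max_lv = 12) {
  stopifnot(inherits(s, "spectra_set"),
            inherits(sel, "deconfound_selection"))
  full_axis <- sel$trait_profile$wavenumbers
  if (length(s$wavenumbers) != length(full_axis) ||
      !isTRUE(all.equal(as.numeric(s$wavenumbers),
                        as.numeric(full_axis)))) {
    stop_nirdecon("spectra axis does not match the selection's axis",
                  "nirdecon_shape_error")
  }
  y <- s$meta[[response]]
  if (is.null(y) || anyNA(y)) {
    stop_nirdecon(sprintf("response '%s' missing for some samples",
                          response), "nirdecon_validation_error")
  }
  X <- s$absorbance[, sel$selected, drop = FALSE]
  max_lv <- min(max_lv, nrow(X) - 2L, ncol(X))
  cv <- loo_cv(X, y, max_lv)
  model <- fit_pls1(X, y, cv$chosen_lv,
                    wavenumbers = s$wavenumbers[sel$selected])
  list(model = model, cv = cv)
}
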