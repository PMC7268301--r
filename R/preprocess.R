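#' Pre-treatment configuration
#'
#' The six pre-treatment variants compared in the workflow: raw spectra,
#' standard normal variate (SNV), 1st and 2nd Savitzky-Golay derivative,
#' and SNV followed by either derivative.  Defaults follow common NIR
#' practice for solid wood: a 15-point window with a 2nd-order polynomial.
#'
#' @param method one of `"raw"`, `"snv"`, `"sg1"`, `"sg2"`, `"snv_sg1"`,
#'   `"snv_sg2"`.
#' @param sg_window odd integer, Savitzky-Golay window size in points.
#' @param sg_polyorder integer polynomial order; must be at least the
#'   derivative order and less than `sg_window`.
#' @return An object of class `preprocess_config`.
#' @export
#' @examples
#' preprocess_config("snv_sg1")
preprocess_config <- function(method = c("raw", "snv", "sg1", "sg2",
                                         "snv_sg1", "snv_sg2"),
                              sg_window = 15, sg_polyorder = 2) {
  method <- match.arg(method)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  deriv <- sg_deriv_order(method)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
    stop_nirdecon("sg_window must be odd and greater than sg_polyorder",
                  "nirdecon_config_error")
  }
  if (deriv > 0 && sg_polyorder < deriv) {
    stop_nirdecon("sg_polyorder must be >= the derivative order",
                  "nirdecon_config_error")
  }
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder),
            class = "preprocess_config")
}

sg_deriv_order <- function(method) {
  switch(method, raw = 0L, snv = 0L, sg1 = 1L, sg2 = 2L,
         snv_sg1 = 1L, snv_sg2 = 2L)
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf("preprocess_config: %s", x$method))
  if (sg_deriv_order(x$method) > 0) {
    cat(sprintf(" (window %d, polyorder %d)", x$sg_window, x$sg_polyorder))
  }
  cat("\n")
  invisible(x)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to mean 0 and unit standard deviation
#' (sample SD, divisor n-1), removing per-spectrum additive offsets and
#' multiplicative scatter: `snv(a*x + b) == snv(x)` for any `a > 0`.
#'
#' @param s a [spectra_set()] whose spectra have at least 2 points and
#'   nonzero spread.
#' @return A `spectra_set` of the same shape.
#' @export
snv <- function(s) {
  validate_spectra_set(s)
  a <- s$absorbance
  m <- rowMeans(a)
  sdev <- sqrt(rowSums((a - m)^2) / (ncol(a) - 1))
  if (any(sdev == 0)) {
    stop_nirdecon(sprintf(
      "zero-variance spectrum for sample '%s': SNV undefined",
      s$meta$sample_id[sdev == 0][1]), "nirdecon_degenerate_error")
  }
  spectra_set(s$wavenumbers, (a - m) / sdev,
              sample_ids = s$meta$sample_id, meta = s$meta)
}

# Central Savitzky-Golay coefficients for the deriv-th derivative, in
# index units (spacing 1), from the local least-squares polynomial fit.
sg_coefficients <- function(window, polyorder, deriv) {
  F <- signal::sgolay(p = polyorder, n = window, m = deriv)
  as.numeric(F[(window + 1) / 2, ])
}

#' Savitzky-Golay derivative
#'
#' Per-point least-squares local polynomial derivative, scaled by the
#' physical wavenumber spacing so that the result is a true derivative
#' with respect to cm-1 (units: absorbance per cm-1 for `deriv = 1`).
#' Edge points for which the full window does not fit are dropped: the
#' wavenumber axis is truncated by `(window - 1) / 2` points on each side
#' rather than padded, so no fabricated edge values can enter variable
#' selection.
#'
#' @param s a [spectra_set()] with at least `window` points.
#' @param deriv derivative order, 1 or 2.
#' @param window odd integer window size in points.
#' @param polyorder polynomial order, `>= deriv` and `< window`.
#' @return A `spectra_set` on the truncated axis.
#' @export
sg_derivative <- function(s, deriv, window = 15, polyorder = 2) {
  validate_spectra_set(s)
  deriv <- as.integer(deriv)
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (!deriv %in% c(1L, 2L)) {
    stop_nirdecon("deriv must be 1 or 2", "nirdecon_config_error")
  }
  if (window %% 2 == 0 || window <= polyorder) {
    stop_nirdecon("window must be odd and greater than polyorder",
                  "nirdecon_config_error")
  }
  if (polyorder < deriv) {
    stop_nirdecon("polyorder must be >= deriv", "nirdecon_config_error")
  }
  p <- length(s$wavenumbers)
  if (p < window) {
    stop_nirdecon(sprintf("need >= %d points for window %d (have %d)",
                          window, window, p), "nirdecon_config_error")
  }
  h <- (window - 1L) / 2L
  cf <- sg_coefficients(window, polyorder, deriv)
  spacing <- diff(s$wavenumbers)[1]
  keep <- (h + 1L):(p - h)
  # banded convolution matrix: out[, j] = sum_k cf[k] * A[, keep[j]-h-1+k]
  conv <- matrix(0, p, length(keep))
  for (j in seq_along(keep)) {
    conv[(keep[j] - h):(keep[j] + h), j] <- cf
  }
  out <- (s$absorbance %*% conv) / spacing^deriv
  spectra_set(s$wavenumbers[keep], out,
              sample_ids = s$meta$sample_id, meta = s$meta)
}

#' Apply a pre-treatment configuration
#'
#' Composes [snv()] and [sg_derivative()] as named by the configuration;
#' for the `snv_*` variants SNV is applied first, then the derivative.
#' `"raw"` returns the input unchanged.
#'
#' @param s a [spectra_set()].
#' @param cfg a [preprocess_config()], or a method name passed to it.
#' @return A `spectra_set`.
#' @export
#' @examples
#' s <- spectra_set(seq(9000, 4000, by = -10),
#'                  matrix(rnorm(3 * 501), 3, 501))
#' ncol(apply_pretreatment(s, "snv_sg1")$absorbance)  # 501 - 14
apply_pretreatment <- function(s, cfg) {
  if (is.character(cfg)) cfg <- preprocess_config(cfg)
  stopifnot(inherits(cfg, "preprocess_config"))
  deriv <- sg_deriv_order(cfg$method)
  out <- s
  if (cfg$method %in% c("snv", "snv_sg1", "snv_sg2")) out <- snv(out)
  if (deriv > 0) {
    out <- sg_derivative(out, deriv, cfg$sg_window, cfg$sg_polyorder)
  }
  out
}
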