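#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min-distance selection of a representative
#' calibration subset: the first two samples are the pair with maximal
#' Euclidean distance; each subsequent selection maximizes the minimum
#' distance to the already-selected set.  Distance ties are broken by the
#' lowest sample index, so the split is fully reproducible.
#'
#' Distances should be computed in the space that will feed the model,
#' i.e. on pre-processed spectra.
#'
#' @param X numeric matrix (samples x variables) or a [spectra_set()].
#' @param n_select number of calibration samples, `2 <= n_select <= n`.
#' @return An object of class `ks_split`: list with `cal_indices` (in
#'   selection order) and `val_indices` (remaining, in original order).
#' @export
#' @examples
#' kennard_stone(matrix(c(0, 1, 10)), 2)$cal_indices  # 1 and 3
kennard_stone <- function(X, n_select) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  n <- nrow(X)
  n_select <- as.integer(n_select)
  if (n_select < 2) {
    stop_nirdecon("n_select must be at least 2", "nirdecon_config_error")
  }
  if (n_select > n) {
    stop_nirdecon(sprintf("n_select (%d) exceeds sample count (%d)",
                          n_select, n), "nirdecon_config_error")
  }
  D <- as.matrix(dist(X))
  # starting pair: maximal distance, ties by smallest (i, j)
  hit <- which(D == max(D), arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- as.integer(hit[1, ])
  remaining <- setdiff(seq_len(n), sel)
  # min distance from each remaining candidate to the selected set
  mind <- pmin(D[remaining, sel[1]], D[remaining, sel[2]])
  while (length(sel) < n_select) {
    pick <- which.max(mind)  # first maximum = lowest index tie-break
    sel <- c(sel, remaining[pick])
    remaining <- remaining[-pick]
    mind <- pmin(mind[-pick], D[remaining, sel[length(sel)]])
  }
  structure(list(cal_indices = sel, val_indices = remaining),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("ks_split: %d calibration / %d validation samples\n",
              length(x$cal_indices), length(x$val_indices)))
  invisible(x)
}
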