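#' Spectral data set
#'
#' Container for a wide-format spectral matrix: a wavenumber axis, an
#' absorbance matrix (rows = samples) and per-sample metadata.  The axis
#' must be strictly monotone with uniform spacing (instrument output is
#' stored descending, 9000 to 4000 cm-1, but all downstream code is
#' order-agnostic).
#'
#' @param wavenumbers numeric vector of wavenumbers (cm-1), strictly
#'   monotone with uniform spacing.
#' @param absorbance numeric matrix, `n_samples x length(wavenumbers)`,
#'   free of NA/NaN/Inf.
#' @param sample_ids unique character vector of sample identifiers;
#'   defaults to `rownames(absorbance)` or `s1, s2, ...`.
#' @param meta data.frame of per-sample metadata with columns `sample_id`,
#'   `core_id`, `ec` (extractives content, percent dry mass, in
#'   \[0, 100\] or NA) and `angle` (degrees, 0 or 90, or NA).  Missing
#'   columns are filled with NA.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `wavenumbers`, `absorbance` and `meta`.
#' @export
#' @examples
#' s <- spectra_set(c(9000, 8990, 8980), matrix(rnorm(6), 2, 3))
#' s$meta
spectra_set <- function(wavenumbers, absorbance, sample_ids = NULL,
                        meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  n <- nrow(absorbance)
  if (is.null(sample_ids)) {
    from_meta <- if (is.list(meta) && length(meta$sample_id) == n)
      meta$sample_id
    sample_ids <- rownames(absorbance) %||% from_meta %||%
      sprintf("s%d", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (n > 0) rownames(absorbance) <- sample_ids
  colnames(absorbance) <- NULL
  meta <- normalize_meta(meta, sample_ids)
  s <- structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance, meta = meta),
    class = "spectra_set"
  )
  validate_spectra_set(s)
  s
}

normalize_meta <- function(meta, sample_ids) {
  n <- length(sample_ids)
  if (is.null(meta)) {
    meta <- data.frame(sample_id = sample_ids,
                       core_id = rep(NA_character_, n),
                       ec = rep(NA_real_, n), angle = rep(NA_real_, n),
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta)) {
      stop_nirdecon("metadata must contain a 'sample_id' column",
                    "nirdecon_format_error")
    }
    meta$sample_id <- as.character(meta$sample_id)
    if (anyDuplicated(meta$sample_id)) {
      stop_nirdecon(
        sprintf("duplicate sample id in metadata: '%s'",
                meta$sample_id[duplicated(meta$sample_id)][1]),
        "nirdecon_validation_error")
    }
    for (col in c("core_id", "ec", "angle")) {
      if (!col %in% names(meta)) meta[[col]] <- NA
    }
    # samples present in spectra but absent from meta get missing metadata
    idx <- match(sample_ids, meta$sample_id)
    meta <- meta[idx, c("sample_id", "core_id", "ec", "angle"),
                 drop = FALSE]
    meta$sample_id <- sample_ids
    rownames(meta) <- NULL
  }
  meta$core_id <- as.character(meta$core_id)
  meta$ec <- as.numeric(meta$ec)
  meta$angle <- as.numeric(meta$angle)
  bad_ec <- !is.na(meta$ec) & (meta$ec < 0 | meta$ec > 100)
  if (any(bad_ec)) {
    stop_nirdecon(
      sprintf("ec out of [0, 100] for sample '%s'",
              meta$sample_id[bad_ec][1]),
      "nirdecon_validation_error")
  }
  bad_angle <- !is.na(meta$angle) & !meta$angle %in% c(0, 90)
  if (any(bad_angle)) {
    stop_nirdecon(
      sprintf("angle must be 0 or 90 degrees; sample '%s' has %g",
              meta$sample_id[bad_angle][1], meta$angle[bad_angle][1]),
      "nirdecon_validation_error")
  }
  meta
}

validate_spectra_set <- function(s) {
  w <- s$wavenumbers
  a <- s$absorbance
  if (ncol(a) != length(w)) {
    stop_nirdecon(sprintf(
      "absorbance has %d columns but %d wavenumbers given",
      ncol(a), length(w)), "nirdecon_validation_error")
  }
  if (length(w) < 2) {
    stop_nirdecon("at least two wavenumbers required",
                  "nirdecon_validation_error")
  }
  d <- diff(w)
  if (d[1] == 0 || any(abs(d - d[1]) > 1e-9 * abs(d[1]))) {
    stop_nirdecon(
      "wavenumber axis must be strictly monotone with uniform spacing",
      "nirdecon_validation_error")
  }
  if (nrow(a) > 0 && any(!is.finite(a))) {
    bad <- which(!is.finite(a), arr.ind = TRUE)[1, ]
    stop_nirdecon(sprintf(
      "non-finite absorbance at sample '%s', wavenumber %g",
      rownames(a)[bad[1]], w[bad[2]]), "nirdecon_validation_error")
  }
  ids <- s$meta$sample_id
  if (anyDuplicated(ids)) {
    stop_nirdecon(sprintf("duplicate sample id: '%s'",
                          ids[duplicated(ids)][1]),
                  "nirdecon_validation_error")
  }
  if (nrow(s$meta) != nrow(a)) {
    stop_nirdecon("metadata row count does not match absorbance rows",
                  "nirdecon_validation_error")
  }
  invisible(s)
}

#' @export
print.spectra_set <- function(x, ...) {
  w <- x$wavenumbers
  cat(sprintf(
    "spectra_set: %d samples x %d wavenumbers (%g to %g cm-1, step %g)\n",
    nrow(x$absorbance), length(w), w[1], w[length(w)], diff(w)[1]))
  n_ec <- sum(!is.na(x$meta$ec))
  n_ang <- sum(!is.na(x$meta$angle))
  cat(sprintf("  metadata: ec for %d, angle for %d of %d samples\n",
              n_ec, n_ang, nrow(x$meta)))
  invisible(x)
}

#' Subset a spectra_set by sample and/or wavenumber
#'
#' @param x a [spectra_set()].
#' @param i sample index (numeric, logical or sample id character).
#' @param j wavenumber column index.
#' @param ... ignored.
#' @return A `spectra_set` with the selected rows/columns.
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$absorbance))
  if (missing(j)) j <- seq_along(x$wavenumbers)
  if (is.character(i)) i <- match(i, x$meta$sample_id)
  spectra_set(x$wavenumbers[j], x$absorbance[i, j, drop = FALSE],
              sample_ids = x$meta$sample_id[i],
              meta = x$meta[i, , drop = FALSE])
}

#' Read spectra and metadata from delimited text files
#'
#' The spectral file is a comma-separated wide table: first column the
#' sample id, remaining column headers numeric wavenumbers.  The metadata
#' file (optional) is keyed by `sample_id` with columns `core_id`, `ec`
#' and `angle`; empty fields are missing values.
#'
#' @param spectra_path path to the wide spectral CSV.
#' @param meta_path path to the metadata CSV, or NULL for no metadata.
#' @return A validated [spectra_set()].
#' @export
read_spectra <- function(spectra_path, meta_path = NULL) {
  tab <- tryCatch(
    suppressWarnings(read.csv(spectra_path, check.names = FALSE,
                              fill = FALSE, colClasses = "character")),
    error = function(e) {
      stop_nirdecon(sprintf("malformed spectra file '%s': %s",
                            spectra_path, conditionMessage(e)),
                    "nirdecon_format_error")
    })
  if (ncol(tab) < 3) {
    stop_nirdecon("spectra file needs an id column and >= 2 wavenumbers",
                  "nirdecon_format_error")
  }
  hdr <- names(tab)[-1]
  w <- suppressWarnings(as.numeric(hdr))
  if (anyNA(w)) {
    stop_nirdecon(sprintf("non-numeric wavenumber header: '%s'",
                          hdr[is.na(w)][1]), "nirdecon_format_error")
  }
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    stop_nirdecon(sprintf("duplicate sample id in spectra file: '%s'",
                          ids[duplicated(ids)][1]),
                  "nirdecon_validation_error")
  }
  a <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[-1])), nrow = nrow(tab),
           ncol = ncol(tab) - 1L))
  if (nrow(tab) > 0 && anyNA(a)) {
    bad_row <- which(rowSums(is.na(a)) > 0)[1]
    stop_nirdecon(sprintf("non-numeric absorbance value in row %d",
                          bad_row), "nirdecon_format_error")
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- tryCatch(suppressWarnings(read.csv(meta_path,
                                               check.names = FALSE)),
                     error = function(e) {
                       stop_nirdecon(sprintf("cannot read metadata '%s': %s",
                                             meta_path, conditionMessage(e)),
                                     "nirdecon_format_error")
                     })
  }
  spectra_set(w, a, sample_ids = ids, meta = meta)
}

#' Write spectra and metadata to delimited text files
#'
#' Inverse of [read_spectra()].  Values are written with 17 significant
#' digits so that a write/read round trip preserves doubles bitwise.
#'
#' @param s a [spectra_set()].
#' @param spectra_path output path for the wide spectral CSV.
#' @param meta_path output path for the metadata CSV, or NULL to skip.
#' @return Invisibly, `s`.
#' @export
write_spectra <- function(s, spectra_path, meta_path = NULL) {
  validate_spectra_set(s)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  hdr <- paste(c("sample_id", fmt(s$wavenumbers)), collapse = ",")
  rows <- character(nrow(s$absorbance))
  if (nrow(s$absorbance) > 0) {
    body <- apply(s$absorbance, 1, function(r) paste(fmt(r), collapse = ","))
    rows <- paste(s$meta$sample_id, body, sep = ",")
  }
  ok <- tryCatch({
    writeLines(c(hdr, rows), spectra_path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    stop_nirdecon(sprintf("cannot write spectra file '%s'", spectra_path),
                  "nirdecon_io_error")
  }
  if (!is.null(meta_path)) {
    m <- s$meta
    m$ec <- fmt(m$ec)
    m$angle <- fmt(m$angle)
    m$core_id <- ifelse(is.na(m$core_id), "", m$core_id)
    write.csv(m, meta_path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(s)
}

#' Average replicate scans per group
#'
#' Reduces multiple scans of the same physical sample (e.g. spectra taken
#' at regular intervals along one increment core) to a single mean
#' spectrum per group.  Metadata fields are retained only if constant
#' within the group, otherwise set missing.
#'
#' @param s a [spectra_set()].
#' @param group_key name of the metadata column defining replicate groups
#'   (default `"core_id"`); must be non-missing for every sample.
#' @return A `spectra_set` with one row per distinct group, in order of
#'   first appearance.
#' @export
average_replicates <- function(s, group_key = "core_id") {
  validate_spectra_set(s)
  if (!group_key %in% names(s$meta)) {
    stop_nirdecon(sprintf("unknown metadata field '%s'", group_key),
                  "nirdecon_validation_error")
  }
  g <- s$meta[[group_key]]
  if (anyNA(g)) {
    stop_nirdecon(sprintf(
      "missing '%s' for sample '%s'", group_key,
      s$meta$sample_id[is.na(g)][1]), "nirdecon_validation_error")
  }
  g <- as.character(g)
  groups <- unique(g)
  gi <- factor(g, levels = groups)
  counts <- as.vector(table(gi))
  a <- rowsum(s$absorbance, gi, reorder = FALSE) / counts
  const_or_na <- function(x) {
    vapply(groups, function(k) {
      v <- unique(x[g == k])
      if (length(v) == 1) v else x[NA_integer_]
    }, FUN.VALUE = x[1], USE.NAMES = FALSE)
  }
  meta <- data.frame(
    sample_id = groups,
    core_id = const_or_na(s$meta$core_id),
    ec = const_or_na(s$meta$ec),
    angle = const_or_na(s$meta$angle),
    stringsAsFactors = FALSE
  )
  spectra_set(s$wavenumbers, a, sample_ids = groups, meta = meta)
}
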