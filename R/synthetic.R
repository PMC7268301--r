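#' Absorption band specification
#'
#' One Gaussian absorption band of the synthetic spectra generator.  The
#' band's contribution to a sample's spectrum is
#' `amplitude * drive * exp(-(wn - center)^2 / (2 width^2))`, where the
#' drive depends on the role: the trait value (`ec`, percent) for
#' `trait_only`, the indicator of the 90-degree angle group for
#' `confounder_only`, `ec + gamma * 1{angle == 90}` for `shared`, and a
#' constant 1 for `inert`.
#'
#' @param center band center, cm-1.
#' @param width Gaussian sigma, cm-1, > 0.
#' @param role one of `"trait_only"`, `"confounder_only"`, `"shared"`,
#'   `"inert"`.
#' @param amplitude absorbance units per unit of driving variable.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(center, width,
                      role = c("trait_only", "confounder_only",
                               "shared", "inert"),
                      amplitude) {
  role <- match.arg(role)
  if (width <= 0) {
    stop_nirdecon("band width must be > 0", "nirdecon_config_error")
  }
  structure(list(center = center, width = width, role = role,
                 amplitude = amplitude), class = "band_spec")
}

#' Default band layout of the synthetic benchmark
#'
#' Mirrors the band geography observed for extractives content and grain
#' angle on solid-wood NIR spectra: trait-specific bands near 6000 and
#' 5400 cm-1, confounder-specific bands in the 8200-7800 cm-1 region,
#' one shared band near 8500 cm-1, and two inert structural bands.
#'
#' @return List of [band_spec()]s.
#' @export
default_bands <- function() {
  list(
    band_spec(6000, 60, "trait_only", 0.0030),
    band_spec(5400, 50, "trait_only", 0.0025),
    band_spec(8100, 70, "confounder_only", 0.045),
    band_spec(7900, 50, "confounder_only", 0.0375),
    band_spec(8500, 60, "shared", 0.0015),
    band_spec(7000, 90, "inert", 0.08),
    band_spec(4500, 70, "inert", 0.06)
  )
}

#' Synthetic NIR spectra configuration
#'
#' Defines the simulated study conditions: sample count and axis of the
#' emulated measurement campaign (237 samples, 9000 to 4000 cm-1 at
#' 10 cm-1 steps), a realistic extractives-content range (uniform on
#' 1.23 to 16.49 percent, mean 8.86), a
#' balanced 0/90-degree angle design, planted absorption bands, a fixed
#' quadratic baseline, per-spectrum multiplicative (log-normal) and
#' additive (Gaussian) scatter, and white noise.
#'
#' @param n_samples number of samples.
#' @param wn_max,wn_min,wn_step wavenumber axis: from `wn_max` down to
#'   `wn_min` in steps of `-wn_step` cm-1.
#' @param bands list of [band_spec()]s; all centers must lie on the axis
#'   range.
#' @param ec_range extractives-content range (percent dry mass).
#' @param angle_fraction probability that a sample is in the 90-degree
#'   group, strictly between 0 and 1.
#' @param shared_angle_coef gamma: the 90-degree offset, in EC units,
#'   driving `shared` bands (sized once so that the full-spectrum trait
#'   model exhibits a clearly significant angle artifact at the default
#'   signal-to-noise ratio).
#' @param scatter_mult_sd SD of the log multiplicative scatter factor.
#' @param scatter_add_sd SD of the additive scatter offset (absorbance).
#' @param noise_sd white-noise SD (absorbance).
#' @param seed integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 237, wn_max = 9000,
                             wn_min = 4000, wn_step = 10,
                             bands = default_bands(),
                             ec_range = c(1.23, 16.49),
                             angle_fraction = 0.5,
                             shared_angle_coef = 3,
                             scatter_mult_sd = 0.05,
                             scatter_add_sd = 0.01,
                             noise_sd = 0.01, seed = 1) {
  if (ec_range[1] >= ec_range[2]) {
    stop_nirdecon("ec_range must satisfy low < high",
                  "nirdecon_config_error")
  }
  if (angle_fraction <= 0 || angle_fraction >= 1) {
    stop_nirdecon("angle_fraction must be strictly between 0 and 1",
                  "nirdecon_config_error")
  }
  if (scatter_mult_sd < 0 || scatter_add_sd < 0 || noise_sd < 0) {
    stop_nirdecon("scatter and noise SDs must be >= 0",
                  "nirdecon_config_error")
  }
  wn <- seq(wn_max, wn_min, by = -abs(wn_step))
  for (b in bands) {
    if (b$center > max(wn) || b$center < min(wn)) {
      stop_nirdecon(sprintf("band center %g cm-1 outside axis [%g, %g]",
                            b$center, min(wn), max(wn)),
                    "nirdecon_config_error")
    }
  }
  structure(list(
    n_samples = as.integer(n_samples), wavenumbers = wn, bands = bands,
    ec_range = ec_range, angle_fraction = angle_fraction,
    shared_angle_coef = shared_angle_coef,
    scatter_mult_sd = scatter_mult_sd, scatter_add_sd = scatter_add_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Indices of the axis within 1.5 sigma of a band center -- the band's
# ground-truth footprint used by recovery tests.  Beyond 1.5 sigma a
# Gaussian band retains less than a third of its peak response, so wider
# footprints would score selection against points the band barely drives.
band_indices <- function(wn, band) {
  which(abs(wn - band$center) <= 1.5 * band$width)
}

#' Generate synthetic NIR spectra with known ground truth
#'
#' Each spectrum is a fixed quadratic baseline plus the Gaussian band
#' contributions described in [band_spec()], distorted by a per-spectrum
#' multiplicative factor (log-normal) and additive offset, plus white
#' noise.  The returned truth records the planted per-sample trait and
#' angle values and the wavenumber footprint of every band role --
#' the targets that selection-recovery experiments are scored against.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `spectra` (a [spectra_set()]) and `truth` (class
#'   `synthetic_truth`: `ec`, `angle`, `bands`, `role_indices`,
#'   `role_wavenumbers`, `wavenumbers`).
#' @export
#' @examples
#' g <- generate_spectra(synthetic_config(n_samples = 20, seed = 7))
#' g$spectra
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  wn <- cfg$wavenumbers
  n <- cfg$n_samples
  p <- length(wn)

  roles <- vapply(cfg$bands, `[[`, "", "role")
  idx_by_role <- lapply(
    c(trait_only = "trait_only", confounder_only = "confounder_only",
      shared = "shared", inert = "inert"),
    function(r) {
      sort(unique(unlist(lapply(cfg$bands[roles == r],
                                function(b) band_indices(wn, b)))))
    })
  if (length(intersect(idx_by_role$trait_only,
                       idx_by_role$confounder_only)) > 0) {
    stop_nirdecon(
      "trait_only and confounder_only band footprints overlap",
      "nirdecon_config_error")
  }

  with_seed(cfg$seed, {
    ec <- runif(n, cfg$ec_range[1], cfg$ec_range[2])
    angle <- ifelse(runif(n) < cfg$angle_fraction, 90, 0)
    ind90 <- as.numeric(angle == 90)

    G <- vapply(cfg$bands, function(b) {
      b$amplitude * exp(-(wn - b$center)^2 / (2 * b$width^2))
    }, numeric(p))                       # p x n_bands
    drive <- vapply(seq_along(cfg$bands), function(k) {
      switch(roles[k],
             trait_only = ec,
             confounder_only = ind90,
             shared = ec + cfg$shared_angle_coef * ind90,
             inert = rep(1, n))
    }, numeric(n))                       # n x n_bands

    xs <- (wn - mean(range(wn))) / (diff(range(wn)) / 2)
    baseline <- 0.45 + 0.30 * xs + 0.15 * xs^2
    A <- matrix(baseline, n, p, byrow = TRUE) + tcrossprod(drive, G)
    mult <- exp(rnorm(n, 0, cfg$scatter_mult_sd))
    offset <- rnorm(n, 0, cfg$scatter_add_sd)
    A <- A * mult + offset
    if (cfg$noise_sd > 0) A <- A + matrix(rnorm(n * p, 0, cfg$noise_sd), n, p)

    ids <- sprintf("s%03d", seq_len(n))
    spectra <- spectra_set(
      wn, A, sample_ids = ids,
      meta = data.frame(sample_id = ids, core_id = ids, ec = ec,
                        angle = angle, stringsAsFactors = FALSE))
    truth <- structure(list(
      ec = ec, angle = angle, bands = cfg$bands,
      role_indices = idx_by_role,
      role_wavenumbers = lapply(idx_by_role, function(i) wn[i]),
      wavenumbers = wn
    ), class = "synthetic_truth")
    list(spectra = spectra, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d samples; band points: %d trait-only, %d confounder-only, %d shared\n",
    length(x$ec), length(x$role_indices$trait_only),
    length(x$role_indices$confounder_only),
    length(x$role_indices$shared)))
  invisible(x)
}

#' Standard deconfounding benchmark
#'
#' The fixed published configuration used throughout the package's
#' validation experiments: 237 samples on the 501-point axis, split into
#' 200 calibration and 37 validation samples by Kennard-Stone on the
#' SNV + 1st-derivative pre-processed spectra (the space that feeds the
#' default model), with the [default_bands()] layout.
#'
#' @param seed integer seed for the generator.
#' @param n_cal number of calibration samples (default 200).
#' @param config optional [synthetic_config()] overriding the defaults;
#'   its `seed` is replaced by `seed`.
#' @return List with `cal` and `val` (raw [spectra_set()]s), `truth`,
#'   `split` (the [kennard_stone()] result) and `config`.
#' @export
default_benchmark <- function(seed = 1, n_cal = 200, config = NULL) {
  cfg <- config %||% synthetic_config()
  cfg$seed <- as.integer(seed)
  g <- generate_spectra(cfg)
  pp <- apply_pretreatment(g$spectra, preprocess_config("snv"))
  split <- kennard_stone(pp$absorbance, n_cal)
  list(cal = g$spectra[split$cal_indices, ],
       val = g$spectra[split$val_indices, ],
       truth = g$truth, split = split, config = cfg)
}
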