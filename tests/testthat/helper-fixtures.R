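# Shared fixtures and independent oracles for the test suite.

# Random spectra_set on a uniform descending axis.
tiny_spectra <- function(n = 5, p = 10, seed = 1, wn_from = 9000, step = 10) {
  set.seed(seed)
  wn <- seq(wn_from, by = -step, length.out = p)
  spectra_set(wn, matrix(rnorm(n * p), n, p))
}

# Independent brute-force implementation of the Kennard-Stone greedy
# rule (plain loops, no shared code with the package implementation).
ks_brute_force <- function(X, k) {
  n <- nrow(X)
  d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
  best <- c(1L, 2L)
  bd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dd <- d2(i, j)
      if (dd > bd) {
        bd <- dd
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < k) {
    remaining <- setdiff(seq_len(n), sel)
    score <- vapply(remaining, function(r) {
      min(vapply(sel, function(s) d2(r, s), numeric(1)))
    }, numeric(1))
    sel <- c(sel, remaining[which.max(score)])
  }
  sel
}

# Small synthetic configuration used where the full 237 x 501 benchmark
# would be needlessly slow: same structure, coarser axis, fewer samples.
small_config <- function(seed = 1, ...) {
  synthetic_config(n_samples = 80, wn_step = 20, seed = seed, ...)
}

# A minimal pipeline config over simulated data, for pipeline tests.
small_pipeline_config <- function(seed = 1) {
  list(
    simulate = list(n_samples = 80, wn_step = 20),
    preprocess = list(method = "snv"),
    split = list(n_cal = 60),
    model = list(max_lv = 6),
    selection = list(alpha = 0.05),
    seed = seed
  )
}

# One full benchmark replicate of the deconfounding workflow, reduced to
# the quantities the validation experiments score.
benchmark_run <- function(seed) {
  b <- default_benchmark(seed = seed)
  rep <- deconfound_report(b$cal, b$val, preprocess = "snv")
  sel <- rep$selection
  tw <- b$truth$role_wavenumbers$trait_only
  cw <- b$truth$role_wavenumbers$confounder_only
  list(
    recovery = mean(tw %in% sel$wavenumbers),
    confounder_points = sum(cw %in% sel$wavenumbers),
    p_full = rep$full$anova$p_value,
    p_reduced = rep$reduced$anova$p_value,
    r2_trait_full = rep$full$val_metrics$r2,
    r2_trait_reduced = rep$reduced$val_metrics$r2,
    r2_angle_full = rep$full$confounder$val_metrics$r2,
    r2_angle_reduced = rep$reduced$confounder$val_metrics$r2,
    n_selected = sel$n_selected
  )
}

# The 20-replicate benchmark experiment is shared by several acceptance
# checks; compute it once per test run, on first use.
benchmark_replicates <- local({
  cache <- NULL
  function(n_seeds = 20) {
    if (is.null(cache)) {
      cache <<- lapply(seq_len(n_seeds), benchmark_run)
    }
    cache
  }
})
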