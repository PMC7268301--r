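test_that("the two-group ANOVA handles regular and degenerate designs", {
  a <- anova_two_group(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(a$f_stat, 0)
  expect_equal(a$p_value, 1)

  a2 <- anova_two_group(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_true(is.infinite(a2$f_stat))
  expect_lt(a2$p_value, 1e-12)

  expect_error(anova_two_group(1:3, c("a", "a", "b")), "fewer than 2")
  expect_error(anova_two_group(1:4, rep("a", 4)), "two groups")

  expect_equal(significance_stars(2e-4), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.2), "")
})

test_that("with two groups F equals the squared pooled t statistic", {
  set.seed(61)
  for (i in 1:50) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    v <- c(rnorm(n1), rnorm(n2, mean = runif(1, -1, 1)))
    g <- rep(c("g0", "g90"), c(n1, n2))
    a <- anova_two_group(v, g)
    tt <- t.test(v ~ g, var.equal = TRUE)  # independent oracle
    expect_equal(a$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("group means are reported per level", {
  a <- anova_two_group(c(1, 3, 10, 14), c(0, 0, 90, 90))
  expect_equal(unname(a$group_means), c(2, 12))
  expect_equal(a$df, c(1, 2))
})

test_that("the pre-treatment grid returns one labelled report per method", {
  set.seed(62)
  g <- generate_spectra(small_config(seed = 62))
  split <- kennard_stone(snv(g$spectra)$absorbance, 60)
  reports <- pretreatment_grid(g$spectra[split$cal_indices, ],
                               g$spectra[split$val_indices, ],
                               "ec", max_lv = 6)
  expect_length(reports, 6)
  expect_setequal(vapply(reports, `[[`, "", "pretreatment"),
                  c("raw", "snv", "sg1", "sg2", "snv_sg1", "snv_sg2"))
  expect_true(all(vapply(reports, function(r) r$val_metrics$r2,
                         numeric(1)) > 0))
})

test_that("a noiseless collinear system is predicted perfectly", {
  set.seed(63)
  s <- tiny_spectra(30, 10, seed = 63)
  s$meta$ec <- 50 + 10 * s$absorbance[, 3]
  reports <- pretreatment_grid(s[1:20, ], s[21:30, ], "ec",
                               methods = "raw", max_lv = 10)
  expect_gt(reports[[1]]$val_metrics$r2, 1 - 1e-6)
})

test_that("SNV-based pre-treatments beat raw spectra under injected scatter", {
  wins <- vapply(1:20, function(s) {
    g <- generate_spectra(synthetic_config(n_samples = 120,
                                           seed = 100 + s,
                                           scatter_mult_sd = 0.4,
                                           scatter_add_sd = 0.03))
    split <- kennard_stone(snv(g$spectra)$absorbance, 90)
    reports <- pretreatment_grid(g$spectra[split$cal_indices, ],
                                 g$spectra[split$val_indices, ],
                                 "ec", methods = c("raw", "snv", "snv_sg1"),
                                 max_lv = 8)
    rmse <- vapply(reports, function(r) r$val_metrics$rmse, numeric(1))
    all(rmse[2:3] < rmse[1])
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("with no planted angle effect both ANOVAs are null", {
  null_bands <- list(
    band_spec(6000, 60, "trait_only", 0.0030),
    band_spec(5400, 50, "trait_only", 0.0025),
    band_spec(8100, 70, "confounder_only", 0),
    band_spec(7900, 50, "confounder_only", 0),
    band_spec(8500, 60, "shared", 0.0015),
    band_spec(7000, 90, "inert", 0.08),
    band_spec(4500, 70, "inert", 0.06))
  both_null <- vapply(1:20, function(s) {
    cfg <- small_config(seed = 200 + s, bands = null_bands,
                        shared_angle_coef = 0)
    g <- generate_spectra(cfg)
    split <- kennard_stone(snv(g$spectra)$absorbance, 60)
    rep <- deconfound_report(g$spectra[split$cal_indices, ],
                             g$spectra[split$val_indices, ],
                             preprocess = "snv", max_lv = 6)
    rep$full$anova$p_value > 0.05 && rep$reduced$anova$p_value > 0.05
  }, logical(1))
  expect_gte(sum(both_null), 18)
})

test_that("the ANOVA is omitted with a warning when one angle group is absent", {
  set.seed(64)
  g <- generate_spectra(small_config(seed = 64))
  s <- g$spectra
  one_angle <- which(s$meta$angle == 0)
  cal <- s[setdiff(seq_len(80), one_angle[1:3]), ]
  val <- s[one_angle[1:3], ]
  rep <- NULL
  w <- capture_warnings(
    rep <- deconfound_report(cal, val, preprocess = "snv", max_lv = 6))
  expect_true(any(grepl("ANOVA omitted", w)))
  expect_null(rep$full$anova)
})
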