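test_that("read_spectra parses a wide table and validates the axis", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,9000,8990,8980",
               "s1,0.1,0.2,0.3",
               "s2,0.4,0.5,0.6"), tmp)
  s <- read_spectra(tmp)
  expect_s3_class(s, "spectra_set")
  expect_equal(nrow(s$absorbance), 2)
  expect_equal(length(s$wavenumbers), 3)
  expect_equal(diff(s$wavenumbers)[1], -10)
  expect_equal(s$meta$sample_id, c("s1", "s2"))

  writeLines(c("sample_id,9000,8990,8975", "s1,1,2,3"), tmp)
  expect_error(read_spectra(tmp), "uniform spacing")

  writeLines(c("sample_id,9000,abc,8980", "s1,1,2,3"), tmp)
  expect_error(read_spectra(tmp), "abc")

  writeLines(c("sample_id,9000,8990,8980", "s1,1,2,3", "s1,4,5,6"), tmp)
  expect_error(read_spectra(tmp), "duplicate sample id")

  writeLines(c("sample_id,9000,8990,8980", "s1,1,2"), tmp)
  expect_error(read_spectra(tmp), "malformed|row")
})

test_that("metadata is joined by sample id, with missing rows allowed", {
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,9000,8990", "a,1,2", "b,3,4"), sp)
  writeLines(c("sample_id,core_id,ec,angle", "b,c1,8.5,90"), mp)
  s <- read_spectra(sp, mp)
  expect_true(is.na(s$meta$ec[1]))
  expect_equal(s$meta$ec[2], 8.5)
  expect_equal(s$meta$angle[2], 90)

  writeLines(c("sample_id,core_id,ec,angle", "b,c1,8.5,45"), mp)
  expect_error(read_spectra(sp, mp), "angle")
  writeLines(c("sample_id,core_id,ec,angle", "b,c1,120,0"), mp)
  expect_error(read_spectra(sp, mp), "ec")
})

test_that("write/read round trip preserves data to double precision", {
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  for (dims in list(c(5, 10), c(100, 501))) {
    s <- tiny_spectra(dims[1], dims[2], seed = dims[1])
    s$meta$ec <- runif(dims[1], 1, 16)
    s$meta$angle <- rep(c(0, 90), length.out = dims[1])
    write_spectra(s, sp, mp)
    s2 <- read_spectra(sp, mp)
    expect_identical(s2$wavenumbers, s$wavenumbers)
    expect_lt(max(abs(s2$absorbance - s$absorbance)), 1e-12)
    expect_equal(s2$meta$ec, s$meta$ec)
  }
})

test_that("an empty spectra_set survives the round trip", {
  sp <- withr::local_tempfile(fileext = ".csv")
  s <- spectra_set(c(9000, 8990, 8980), matrix(numeric(0), 0, 3))
  write_spectra(s, sp)
  s2 <- read_spectra(sp)
  expect_equal(nrow(s2$absorbance), 0)
  expect_identical(s2$wavenumbers, s$wavenumbers)
})

test_that("spectra_set enforces its invariants", {
  expect_error(spectra_set(c(9000, 8990), matrix(1, 1, 3)),
               "columns")
  expect_error(spectra_set(c(9000, 8990, 8985), matrix(1, 1, 3)),
               "uniform spacing")
  expect_error(spectra_set(c(9000, 8990), matrix(c(1, NaN), 1, 2)),
               "non-finite")
  expect_error(
    spectra_set(c(9000, 8990), matrix(1, 2, 2),
                sample_ids = c("a", "a")),
    "duplicate")
})

test_that("average_replicates averages within groups and handles metadata", {
  wn <- c(9000, 8990, 8980)
  a <- rbind(c(0, 0, 0), c(2, 2, 2), c(5, 5, 5))
  meta <- data.frame(sample_id = c("x1", "x2", "y1"),
                     core_id = c("g1", "g1", "g2"),
                     ec = c(4, 4, 9), angle = c(0, 90, 0))
  s <- spectra_set(wn, a, meta = meta)
  avg <- average_replicates(s, "core_id")
  expect_equal(nrow(avg$absorbance), 2)
  expect_equal(unname(avg$absorbance[1, ]), c(1, 1, 1))
  expect_equal(avg$meta$ec, c(4, 9))          # constant within group
  expect_true(is.na(avg$meta$angle[1]))       # varies within group
  expect_equal(avg$meta$angle[2], 0)

  # idempotent on a group of identical spectra
  s2 <- spectra_set(wn, rbind(c(1, 2, 3), c(1, 2, 3)),
                    meta = data.frame(sample_id = c("a", "b"),
                                      core_id = "g", ec = NA, angle = NA))
  expect_equal(unname(average_replicates(s2, "core_id")$absorbance[1, ]),
               c(1, 2, 3))

  # six-member group mean matches an independently computed column mean
  set.seed(42)
  a6 <- matrix(rnorm(18), 6, 3)
  s6 <- spectra_set(wn, a6,
                    meta = data.frame(sample_id = paste0("r", 1:6),
                                      core_id = "g", ec = NA, angle = NA))
  expect_lt(max(abs(average_replicates(s6, "core_id")$absorbance[1, ] -
                      colSums(a6) / 6)), 1e-12)

  s$meta$core_id[2] <- NA
  expect_error(average_replicates(s, "core_id"), "missing")
})

test_that("subsetting keeps rows, metadata and axis aligned", {
  s <- tiny_spectra(4, 6, seed = 3)
  s$meta$ec <- 1:4
  sub <- s[c(2, 4), ]
  expect_equal(sub$meta$ec, c(2, 4))
  expect_equal(sub$absorbance, s$absorbance[c(2, 4), ])
  expect_equal(s[, 2:4]$wavenumbers, s$wavenumbers[2:4])
})
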