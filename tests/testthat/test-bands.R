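test_that("integrate_band recovers the closed-form Gaussian area", {
  wn <- seq(1700, 1200, by = -4)
  s <- ftir_spectrum(wn, exp(-0.5 * ((wn - 1452) / 10)^2), "g")
  a <- integrate_band(s, 1452 - 60, 1452 + 60)
  expect_equal(a, 10 * sqrt(2 * pi), tolerance = 0.01)
  zero <- ftir_spectrum(wn, rep(0, length(wn)), "z")
  expect_identical(integrate_band(zero, 1400, 1500), 0)
})

test_that("integrate_band matches a 0.1 cm^-1 Riemann oracle within 0.1%", {
  f <- function(x) {
    0.4 * exp(-0.5 * ((x - 1452) / 9)^2) +
      0.15 * exp(-0.5 * ((x - 1410) / 14)^2) + 0.02 + 1e-5 * x
  }
  wn <- seq(1600, 1300, by = -4)
  s <- ftir_spectrum(wn, f(wn), "mix")
  a <- integrate_band(s, 1424, 1484)
  oracle <- riemann_band_area(f, 1424, 1484, step = 0.1)
  expect_lt(abs(a - oracle) / abs(oracle), 0.001)
})

test_that("integrate_band is linear in the spectrum", {
  wn <- seq(1600, 1300, by = -4)
  set.seed(31)
  y1 <- rnorm(length(wn))
  y2 <- rnorm(length(wn))
  s1 <- ftir_spectrum(wn, y1, "s1")
  s2 <- ftir_spectrum(wn, y2, "s2")
  combo <- ftir_spectrum(wn, 2.5 * y1 - 0.7 * y2, "c")
  expect_equal(integrate_band(combo, 1420, 1490),
               2.5 * integrate_band(s1, 1420, 1490) -
                 0.7 * integrate_band(s2, 1420, 1490),
               tolerance = 1e-10)
})

test_that("narrow windows are rejected", {
  wn <- seq(1600, 1300, by = -4)
  s <- ftir_spectrum(wn, rnorm(length(wn)), "s")
  expect_error(integrate_band(s, 1450, 1455), "3 grid points")
})

test_that("band tables have one row per sample and one column per band", {
  ch <- generate_cohort(tiny_config(seed = 15))
  tab <- band_table(ch)
  expect_s3_class(tab, "band_area_table")
  expect_equal(nrow(tab), 21)
  expect_length(grep("^area_", names(tab)), 6)
  expect_true(all(is.finite(as.matrix(tab[grep("^area_", names(tab))]))))
})

test_that("band areas are invariant to per-sample gain", {
  ch <- generate_cohort(tiny_config(seed = 16))
  tab <- band_table(ch)
  set.seed(7)
  gains <- runif(length(ch$spectra), 0.5, 2)
  ch2 <- ch
  ch2$spectra <- lapply(seq_along(ch$spectra), function(i) {
    s <- ch$spectra[[i]]
    ftir_spectrum(s$wavenumber, gains[i] * s$absorbance, s$sample_id)
  })
  tab2 <- band_table(ch2)
  for (col in grep("^area_", names(tab), value = TRUE)) {
    expect_equal(tab2[[col]], tab[[col]], tolerance = 1e-9)
  }
})

test_that("a flat-zero cohort yields areas of exactly zero", {
  ch <- generate_cohort(tiny_config(seed = 1))
  zero <- lapply(ch$spectra, function(s) {
    ftir_spectrum(s$wavenumber, rep(0, length(s$wavenumber)), s$sample_id)
  })
  ch0 <- ftir_cohort(zero, ch$records)
  tab <- band_table(ch0, config = preprocess_config(baseline = "none",
                                                    normalization = "none"))
  expect_true(all(as.matrix(tab[grep("^area_", names(tab))]) == 0))
})

test_that("degenerate within-group variance is flagged with p = 0", {
  tab <- data.frame(
    sample_id = sprintf("s%02d", 1:9),
    group = rep(c("ND", "D", "D+I"), each = 3),
    glycemia_mgdl = rep(c(83, 500, 81), each = 3),
    area_x = rep(c(1, 0.4, 1), each = 3))
  class(tab) <- c("band_area_table", "data.frame")
  cmp <- compare_groups(tab, "x")
  expect_true(cmp$degenerate)
  expect_identical(cmp$anova_p, 0)
  tab$area_x[1] <- 1.001 # tiny within-group variance: regular path
  expect_false(compare_groups(tab, "x")$degenerate)
})

test_that("groups with fewer than two samples are rejected", {
  tab <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                    group = c("ND", "ND", "D", "D", "D+I"),
                    glycemia_mgdl = c(80, 85, 500, 490, 79),
                    area_x = c(1, 1.1, 0.5, 0.4, 1.05))
  class(tab) <- c("band_area_table", "data.frame")
  expect_error(compare_groups(tab, "x"), "2 samples")
})

test_that("Tukey separates D from ND but not D+I from ND under defaults", {
  ch <- generate_cohort(tiny_config(seed = 1))
  tab <- band_table(ch)
  for (b in c("1452", "836")) {
    cmp <- compare_groups(tab, b)
    expect_lt(cmp$tukey["D-ND", "p adj"], 0.05)
    expect_gt(cmp$tukey["D+I-ND", "p adj"], 0.05)
    expect_lt(cmp$anova_p, 0.05)
  }
})

test_that("glycemia correlation is exact on affine data", {
  tab <- data.frame(sample_id = sprintf("s%02d", 1:10),
                    group = rep(c("ND", "D"), each = 5),
                    glycemia_mgdl = seq(80, 500, length.out = 10))
  tab$area_x <- -0.002 * tab$glycemia_mgdl + 3
  class(tab) <- c("band_area_table", "data.frame")
  res <- glycemia_correlation(tab, "x")
  expect_equal(res$r, -1, tolerance = 1e-12)
  tab$area_x <- rep(1, 10)
  expect_error(glycemia_correlation(tab, "x"), "variance")
})

test_that("Pearson r is affine-invariant with a sign flip under negation", {
  ch <- generate_cohort(tiny_config(seed = 17))
  tab <- band_table(ch)
  base <- glycemia_correlation(tab, "1452")$r
  tab2 <- tab
  tab2$area_1452 <- -3 * tab$area_1452 + 10
  expect_equal(glycemia_correlation(tab2, "1452")$r, -base,
               tolerance = 1e-12)
})

test_that("permuted glycemia decorrelates band areas", {
  cfg <- cohort_config(
    n_per_group = c("ND" = 334L, "D" = 333L, "D+I" = 333L),
    baseline_scale = 0, scatter_sd = 0, seed = 23)
  ch <- generate_cohort(cfg)
  tab <- band_table(ch, config = preprocess_config(baseline = "none",
                                                   normalization = "none"))
  set.seed(91)
  tab$glycemia_mgdl <- sample(tab$glycemia_mgdl)
  expect_lt(abs(glycemia_correlation(tab, "1452")$r), 0.1)
})
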