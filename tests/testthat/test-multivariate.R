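test_that("PCA of two samples puts all variance on PC1", {
  x <- rbind(c(1, 0, 2), c(3, 1, 0))
  p <- pca_fit(x)
  expect_equal(p$prop_var[1], 1, tolerance = 1e-12)
  expect_length(p$sdev, 1)
})

test_that("PCA agrees with an SVD oracle up to sign", {
  set.seed(41)
  for (dims in list(c(15, 8), c(6, 60))) { # tall and wide matrices
    x <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    p <- pca_fit(x)
    xc <- scale(x, scale = FALSE)
    sv <- svd(xc)
    k <- length(p$sdev)
    expect_equal(p$sdev, (sv$d / sqrt(dims[1] - 1))[seq_len(k)],
                 tolerance = 1e-8)
    for (j in seq_len(k)) {
      dotprod <- abs(sum(p$loadings[, j] * sv$v[, j]))
      expect_equal(dotprod, 1, tolerance = 1e-8)
    }
  }
})

test_that("loadings are orthonormal and reconstruction is exact", {
  set.seed(42)
  x <- matrix(rnorm(12 * 30), 12, 30)
  p <- pca_fit(x)
  gram <- crossprod(p$loadings)
  expect_equal(gram, diag(ncol(p$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  xc <- sweep(x, 2, p$center)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, xc, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$prop_var) <= 1e-12))
  expect_lte(sum(p$prop_var), 1 + 1e-12)
})

test_that("a constant channel does not change the nonzero components", {
  set.seed(43)
  x <- matrix(rnorm(10 * 20), 10, 20)
  p1 <- pca_fit(x)
  p2 <- pca_fit(cbind(x, 5))
  expect_equal(p1$sdev, p2$sdev, tolerance = 1e-10)
  expect_equal(p1$prop_var, p2$prop_var, tolerance = 1e-10)
})

test_that("select_pcs applies the cumulative-variance rule", {
  props <- c(0.390, 0.320, 0.113, 0.082, 0.031, 0.022, 0.015, 0.01)
  expect_identical(select_pcs(props, target_cumvar = 0.958), 6L)
  expect_identical(select_pcs(1.0, target_cumvar = 0.9), 1L)
  expect_identical(select_pcs(c(0.6, 0.4), target_cumvar = 1.0), 2L)
  expect_identical(select_pcs(props, k = 4), 4L)
  expect_identical(select_pcs(props, k = 100), 8L)
})

test_that("LDA recovers the analytic boundary of two spherical Gaussians", {
  set.seed(44)
  n <- 400
  mu1 <- c(0, 0)
  mu2 <- c(3, 1)
  x <- rbind(matrix(rnorm(2 * n), n, 2) + rep(mu1, each = n),
             matrix(rnorm(2 * n), n, 2) + rep(mu2, each = n))
  lab <- rep(c("a", "b"), each = n)
  fit <- lda_fit(x, lab)
  w <- fit$coef[, "b"] - fit$coef[, "a"] # boundary normal
  w_true <- mu2 - mu1 # spherical covariance: normal is the mean difference
  cosang <- sum(w * w_true) / sqrt(sum(w^2) * sum(w_true^2))
  expect_gt(cosang, cos(5 * pi / 180))
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(45)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 2), 20, 2),
             matrix(rnorm(40, c(0, 3)), 20, 2))
  lab <- rep(c("ND", "D", "D+I"), each = 20)
  fit <- lda_fit(x, lab, prior = "equal")
  ref <- MASS::lda(x, grouping = factor(lab, levels = c("ND", "D", "D+I")),
                   prior = rep(1 / 3, 3))
  mine <- predict(fit, x)$class
  theirs <- predict(ref, x)$class
  expect_gt(mean(as.character(mine) == as.character(theirs)), 0.97)
})

test_that("degenerate LDA cases behave as documented", {
  set.seed(46)
  m <- matrix(rnorm(20), 10, 2)
  x <- rbind(m, m) # identical class means and scatter: exact score tie
  lab <- rep(c("a", "b"), each = 10)
  fit <- lda_fit(x, lab)
  expect_warning(pr <- predict(fit, c(0, 0)), "tie")
  expect_identical(as.character(pr$class), "a") # first class in label order
  expect_error(lda_fit(matrix(rnorm(20), 10, 2), rep("a", 10)), "2 classes")
  expect_error(lda_fit(matrix(rnorm(6), 3, 2), c("a", "a", "b")),
               ">= 2 samples")
})

test_that("LOOCV is perfect on replicated noiseless class prototypes", {
  cfg <- cohort_config(baseline_scale = 0, scatter_sd = 0, noise_sd = 0,
                       glycemia = glycemia_model(
                         sd = c("ND" = 0, "D" = 0, "D+I" = 0)),
                       seed = 1)
  ch <- generate_cohort(cfg)
  # identical prototypes within groups: add microscopic jitter so the
  # within-class covariance is well-defined after regularization
  ch$spectra <- lapply(seq_along(ch$spectra), function(i) {
    s <- ch$spectra[[i]]
    set.seed(i)
    ftir_spectrum(s$wavenumber, s$absorbance + rnorm(length(s$absorbance),
                                                     0, 1e-9),
                  s$sample_id)
  })
  cv <- loocv_pca_lda(ch)
  expect_equal(cv$accuracy, 100)
})

test_that("LOOCV confuses D+I with D before ND with D under boundary overlap", {
  # insulin under-dosing scenario: D+I glycemia intermediate and variable,
  # pushing some treated animals toward the diabetic side of the boundary
  cfg <- cohort_config(
    bands = default_band_specs(0.4),
    glycemia = glycemia_model(mean = c("ND" = 83.2, "D" = 497.6,
                                       "D+I" = 380),
                              sd = c("ND" = 4.2, "D" = 19.6,
                                     "D+I" = 90)),
    seed = 3)
  ch <- generate_cohort(cfg)
  cv <- loocv_pca_lda(ch)
  cm <- cv$confusion
  di_d_errors <- cm["D+I", "D"] + cm["D", "D+I"]
  nd_d_errors <- cm["ND", "D"] + cm["D", "ND"]
  expect_gte(di_d_errors, nd_d_errors)
  expect_gt(di_d_errors, 0)
})

test_that("Ward linkage reproduces the brute-force agglomeration oracle", {
  for (seed in 1:3) {
    cfg <- cohort_config(n_per_group = c("ND" = 4L, "D" = 4L, "D+I" = 4L),
                         seed = seed)
    ch <- generate_cohort(cfg)
    h <- hca(ch, k = 3)
    oracle <- ward_bruteforce(salivaftir:::hca_features(ch))
    expect_equal(h$height, oracle$heights, tolerance = 1e-8)
    expect_identical(hclust_partitions(h$hclust), oracle$partitions)
  }
})

test_that("Ward merge heights are monotone non-decreasing", {
  ch <- generate_cohort(tiny_config(seed = 24))
  h <- hca(ch)
  expect_true(all(diff(h$height) >= -1e-12))
})

test_that("duplicated spectra merge first at height zero", {
  ch <- generate_cohort(tiny_config(seed = 25))
  dup <- ch$spectra[[1]]
  dup <- ftir_spectrum(dup$wavenumber, dup$absorbance, "ND_dup")
  rec <- rbind(ch$records,
               data.frame(sample_id = "ND_dup", group = "ND",
                          glycemia_mgdl = ch$records$glycemia_mgdl[1]))
  ch2 <- ftir_cohort(c(ch$spectra, list(dup)), rec)
  h <- hca(ch2)
  expect_equal(h$height[1], 0, tolerance = 1e-12)
  first <- h$hclust$merge[1, ]
  labs <- h$hclust$labels[-first]
  expect_setequal(labs, c("ND_01", "ND_dup"))
})

test_that("well-separated synthetic groups cluster perfectly", {
  ch <- generate_cohort(cohort_config(bands = default_band_specs(3),
                                      seed = 26))
  h <- hca(ch)
  expect_equal(h$accuracy, 100)
  expect_equal(length(unique(h$mapping)), 3)
  expect_error(hca(ch, k = 50), "exceeds")
})

test_that("dendrogram exports are well-formed", {
  ch <- generate_cohort(tiny_config(seed = 27))
  h <- hca(ch)
  pj <- tempfile(fileext = ".json")
  export_dendrogram(h, pj, "json")
  tree <- jsonlite::read_json(pj)
  expect_true(!is.null(tree$height))
  count_leaves <- function(nd) {
    if (!is.null(nd$label)) 1L else
      sum(vapply(nd$children, count_leaves, integer(1)))
  }
  expect_identical(count_leaves(tree), 21L)
  skip_if_not_installed("ape")
  pn <- tempfile(fileext = ".nwk")
  export_dendrogram(h, pn, "newick")
  phy <- ape::read.tree(pn)
  expect_equal(length(phy$tip.label), 21)
  unlink(c(pj, pn))
})
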