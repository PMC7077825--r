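test_that("confusion metrics follow their definitions", {
  m <- confusion_metrics(tp = 6, tn = 14, fp = 1, fn = 0)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100 * 14 / 15)
  expect_equal(round(m$specificity, 2), 93.33)
  expect_equal(round(confusion_metrics(tp = 6, tn = 14, fp = 1,
                                       fn = 0)$accuracy, 1), 95.2)
  expect_error(confusion_metrics(tp = 0, tn = 5, fp = 2, fn = 0),
               "sensitivity")
  expect_error(confusion_metrics(tp = 3, tn = 0, fp = 0, fn = 1),
               "specificity")
})

test_that("perfectly separated classes give AUC 1 and a perfect cutoff", {
  scores <- c(1, 2, 3, 5, 6, 7)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE) # low = positive
  curve <- roc_curve(scores, labels, direction = "lower")
  expect_equal(curve$auc, 1)
  cut <- select_cutoff(curve)
  expect_equal(cut$sensitivity, 100)
  expect_equal(cut$specificity, 100)
  expect_equal(cut$youden_j, 1)
  expect_gt(cut$cutoff, 3)
  expect_lt(cut$cutoff, 5)
})

test_that("AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    pos <- seq_len(n) %in% sample(n, sample(3:(n - 3), 1))
    scores <- round(rnorm(n, ifelse(pos, -0.5, 0.5)), 1) # forces ties
    for (dir in c("lower", "higher")) {
      curve <- roc_curve(scores, pos, direction = dir)
      expect_equal(curve$auc, mann_whitney_auc(scores, pos, dir),
                   tolerance = 1e-12)
    }
  }
})

test_that("reversing orientation maps AUC to 1 - AUC", {
  set.seed(55)
  scores <- rnorm(30)
  pos <- rep(c(TRUE, FALSE), 15)
  a1 <- roc_curve(scores, pos, direction = "lower")$auc
  a2 <- roc_curve(scores, pos, direction = "higher")$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(77)
  scores <- rexp(40) + 0.1
  pos <- rep(c(TRUE, FALSE), 20)
  a <- roc_curve(scores, pos, direction = "lower")$auc
  expect_equal(roc_curve(log(scores), pos, direction = "lower")$auc, a)
  expect_equal(roc_curve(scores^3, pos, direction = "lower")$auc, a)
})

test_that("the Youden maximizer agrees with exhaustive threshold search", {
  ch <- generate_cohort(tiny_config(seed = 18))
  tab <- band_table(ch)
  scores <- tab$area_1452
  pos <- tab$group == "D"
  curve <- roc_curve(scores, pos, direction = "lower")
  cut <- select_cutoff(curve)
  # brute force over a fine threshold sweep
  grid <- seq(min(scores) - 0.01, max(scores) + 0.01, length.out = 5000)
  j_grid <- vapply(grid, function(t) {
    cp <- scores < t
    sum(cp & pos) / sum(pos) + sum(!cp & !pos) / sum(!pos) - 1
  }, numeric(1))
  expect_equal(cut$youden_j, max(j_grid), tolerance = 1e-9)
})

test_that("identical class distributions give J near zero", {
  scores <- rep(c(1, 2, 3), 4)
  pos <- rep(c(TRUE, FALSE), 6)
  cut <- select_cutoff(roc_curve(scores, pos, direction = "lower"))
  expect_equal(cut$youden_j, 0, tolerance = 1e-12)
})

test_that("reported sensitivity/specificity reproduce from the raw scores", {
  ch <- generate_cohort(tiny_config(seed = 19))
  tab <- band_table(ch)
  for (cmpr in c("normo_vs_D", "DI_vs_D")) {
    ev <- evaluate_band(tab, "836", cmpr)
    keep <- if (cmpr == "normo_vs_D") rep(TRUE, nrow(tab)) else
      tab$group %in% c("D", "D+I")
    counts <- salivaftir:::apply_cutoff(tab$area_836[keep],
                                        tab$group[keep] == "D",
                                        ev$cutoff$cutoff,
                                        direction = "lower")
    m <- confusion_metrics(counts$tp, counts$tn, counts$fp, counts$fn)
    expect_equal(m$sensitivity, ev$cutoff$sensitivity)
    expect_equal(m$specificity, ev$cutoff$specificity)
  }
})

test_that("roc_curve enforces its preconditions", {
  expect_error(roc_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE)), "classes")
  expect_error(roc_curve(c(1, 1, 1), c(TRUE, FALSE, TRUE)), "distinct")
})

test_that("evaluate_band pools the right negatives and checks groups", {
  ch <- generate_cohort(tiny_config(seed = 20))
  tab <- band_table(ch)
  ev <- evaluate_band(tab, "1452", "normo_vs_D")
  expect_equal(ev$roc$n_pos, 6)
  expect_equal(ev$roc$n_neg, 15) # ND and D+I pooled
  ev2 <- evaluate_band(tab, "1452", "DI_vs_D")
  expect_equal(ev2$roc$n_neg, 7) # only D+I
  no_di <- tab[tab$group != "D+I", ]
  class(no_di) <- class(tab)
  expect_error(evaluate_band(no_di, "1452", "DI_vs_D"), "D\\+I")
})

test_that("cross-check against pROC on the default cohort", {
  skip_if_not_installed("pROC")
  ch <- generate_cohort(tiny_config(seed = 22))
  tab <- band_table(ch)
  curve <- roc_curve(tab$area_1452, tab$group == "D", direction = "lower")
  ref <- suppressMessages(pROC::roc(
    response = tab$group == "D", predictor = tab$area_1452,
    direction = ">", quiet = TRUE))
  expect_equal(curve$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("a group-neutral band scores near the null AUC", {
  cfg <- cohort_config(
    n_per_group = c("ND" = 40L, "D" = 40L, "D+I" = 40L), seed = 29)
  ch <- generate_cohort(cfg)
  tab <- band_table(ch, band_definition("f1040", 1040, 1000, 1080),
                    preprocess_config(baseline = "none",
                                      normalization = "none"))
  curve <- roc_curve(tab$area_f1040, tab$group == "D", direction = "lower")
  expect_lt(abs(curve$auc - 0.5), 0.15) # within the null band at n = 120
})
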