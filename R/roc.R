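#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Percentages on the 0-100 scale, at full precision (round only when
#' reporting): sensitivity = 100 TP/(TP+FN), specificity = 100 TN/(TN+FP),
#' accuracy = 100 (TP+TN)/total. The positive class throughout this package
#' is the hyperglycemic diabetic group (D).
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A list with `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' confusion_metrics(tp = 6, tn = 14, fp = 1, fn = 0)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0) {
    stop("sensitivity undefined: no positive samples (TP + FN = 0)",
         call. = FALSE)
  }
  if (tn + fp == 0) {
    stop("specificity undefined: no negative samples (TN + FP = 0)",
         call. = FALSE)
  }
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       accuracy = 100 * (tp + tn) / (tp + tn + fp + fn))
}

#' ROC curve of a continuous score
#'
#' Threshold sweep over the midpoints between adjacent distinct scores plus
#' the two infinite endpoints; tied scores share a threshold. With
#' `direction = "lower"` (the package default: diagnostic band areas
#' *decrease* under hyperglycemia) a sample is called positive when its
#' score falls at or below the cutoff. The AUC is the trapezoidal area under
#' the (1-specificity, sensitivity) polygon and equals the tie-corrected
#' Mann-Whitney U statistic divided by `n_pos * n_neg`. A two-sided
#' Mann-Whitney p-value against AUC = 0.5 is attached.
#'
#' @param scores Numeric scores (e.g. normalized band areas).
#' @param labels Logical or factor/character; `TRUE` (or `positive`) marks
#'   the positive class.
#' @param positive Positive class label when `labels` is not logical.
#' @param direction `"lower"` if low scores indicate the positive class,
#'   `"higher"` otherwise.
#' @return An object of class `ftir_roc`: `points` (data frame of `cutoff`,
#'   `sensitivity`, `specificity`, `tp`, `tn`, `fp`, `fn`), `auc`, `p_value`,
#'   `direction`, `positive`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = "D",
                      direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  pos <- if (is.logical(labels)) labels else as.character(labels) == positive
  if (length(scores) != length(pos)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present (positives: ", n_pos,
         ", negatives: ", n_neg, ")", call. = FALSE)
  }
  if (length(unique(scores)) < 2) {
    stop("need at least 2 distinct scores", call. = FALSE)
  }
  s <- if (direction == "lower") -scores else scores
  u <- sort(unique(s))
  thr <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  # cumulative class counts at or below each distinct score
  o <- order(s)
  pos_le <- cumsum(pos[o])
  idx_last <- cumsum(tabulate(match(s[o], u), nbins = length(u)))
  pos_le_u <- pos_le[idx_last]
  neg_le_u <- idx_last - pos_le_u
  tp <- n_pos - c(0L, pos_le_u) # predicted positive: oriented score > thr
  fp <- n_neg - c(0L, neg_le_u)
  pts <- data.frame(cutoff = if (direction == "lower") -thr else thr,
                    sensitivity = tp / n_pos,
                    specificity = (n_neg - fp) / n_neg,
                    tp = tp, tn = n_neg - fp, fp = fp, fn = n_pos - tp)
  o <- order(1 - pts$specificity, pts$sensitivity)
  fpr <- (1 - pts$specificity)[o]
  tpr <- pts$sensitivity[o]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  pv <- tryCatch(
    suppressWarnings(stats::wilcox.test(scores[pos], scores[!pos],
                                        alternative = "two.sided")$p.value),
    error = function(e) NA_real_)
  structure(list(points = pts, auc = auc, p_value = pv,
                 direction = direction, positive = positive,
                 n_pos = n_pos, n_neg = n_neg),
            class = "ftir_roc")
}

#' @export
print.ftir_roc <- function(x, ...) {
  cat("ROC curve (positive = ", x$positive, ", ", x$direction,
      "-is-positive): AUC = ", sprintf("%.3f", x$auc),
      ", Mann-Whitney p = ", format.pval(x$p_value, digits = 3),
      " (", x$n_pos, " pos / ", x$n_neg, " neg)\n", sep = "")
  invisible(x)
}

#' @export
plot.ftir_roc <- function(x, ...) {
  o <- order(1 - x$points$specificity, x$points$sensitivity)
  graphics::plot(1 - x$points$specificity[o], x$points$sensitivity[o],
                 type = "l", xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Select a diagnostic cutoff from a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 (the field default
#' for biomarker cutoffs). Ties are broken toward higher specificity, then
#' toward the lower cutoff value.
#'
#' @param curve An `ftir_roc` from [roc_curve()].
#' @param rule Only `"youden"` is implemented.
#' @return A list of class `cutoff_result`: `cutoff` (score units),
#'   `sensitivity` and `specificity` (percent), `youden_j`, and the
#'   confusion `counts`.
#' @export
select_cutoff <- function(curve, rule = c("youden")) {
  rule <- match.arg(rule)
  stopifnot(inherits(curve, "ftir_roc"))
  p <- curve$points
  j <- p$sensitivity + p$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-p$specificity[best], p$cutoff[best])]
  i <- best[1]
  structure(list(cutoff = p$cutoff[i],
                 sensitivity = 100 * p$sensitivity[i],
                 specificity = 100 * p$specificity[i],
                 youden_j = j[i],
                 counts = list(tp = p$tp[i], tn = p$tn[i], fp = p$fp[i],
                               fn = p$fn[i]),
                 direction = curve$direction),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "Cutoff %.4g (%s-is-positive): sensitivity %.2f%%, specificity %.2f%%, J = %.3f\n",
    x$cutoff, x$direction, x$sensitivity, x$specificity, x$youden_j))
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n", x$counts$tp,
              x$counts$tn, x$counts$fp, x$counts$fn))
  invisible(x)
}

# re-apply a cutoff to raw scores; used for self-consistency checks
apply_cutoff <- function(scores, labels, cutoff, positive = "D",
                         direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  pos <- if (is.logical(labels)) labels else as.character(labels) == positive
  call_pos <- if (direction == "lower") scores < cutoff else scores > cutoff
  list(tp = sum(call_pos & pos), tn = sum(!call_pos & !pos),
       fp = sum(call_pos & !pos), fn = sum(!call_pos & pos))
}

#' ROC evaluation of one band for a diagnostic comparison
#'
#' Two clinically motivated contrasts: `"normo_vs_D"` pools the
#' normoglycemic groups (ND and D+I) as negatives against the hyperglycemic
#' D positives; `"DI_vs_D"` uses only the insulin-treated group as negatives
#' (the treatment-monitoring question). D is always the positive class and
#' lower band areas indicate disease.
#'
#' @param table A [band_table()] result.
#' @param band_label Band to evaluate.
#' @param comparison `"normo_vs_D"` or `"DI_vs_D"`.
#' @return A list with elements `roc` ([roc_curve()] result), `cutoff`
#'   ([select_cutoff()] result), `band` and `comparison`.
#' @export
evaluate_band <- function(table, band_label,
                          comparison = c("normo_vs_D", "DI_vs_D")) {
  comparison <- match.arg(comparison)
  area <- area_column(table, band_label)
  group <- as_group(table$group)
  need <- if (comparison == "normo_vs_D") group_levels() else c("D", "D+I")
  have <- intersect(need, as.character(unique(group)))
  if (!setequal(have, need)) {
    stop("comparison '", comparison, "' needs group(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  }
  keep <- if (comparison == "normo_vs_D") rep(TRUE, length(group))
          else group %in% c("D", "D+I")
  curve <- roc_curve(area[keep], group[keep] == "D", direction = "lower")
  list(roc = curve, cutoff = select_cutoff(curve), band = band_label,
       comparison = comparison)
}
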