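#' Diagnostic band definitions
#'
#' A band definition is a labelled center wavenumber with an explicit
#' integration window. `default_bands()` returns the six saliva bands used
#' throughout the package with literature-based windows (the window is an
#' explicit, reproducible input — it is never inferred from the data).
#'
#' @param label Band label.
#' @param center_cm1 Band center, cm^-1.
#' @param lo_cm1,hi_cm1 Integration window bounds; `lo < center < hi`.
#' @param assignment Free-text vibrational assignment.
#' @return A data frame of class `band_table_def` with one row per band.
#' @export
band_definition <- function(label, center_cm1, lo_cm1, hi_cm1,
                            assignment = "") {
  stopifnot(length(label) == length(center_cm1),
            length(label) == length(lo_cm1),
            length(label) == length(hi_cm1))
  if (any(!(lo_cm1 < center_cm1 & center_cm1 < hi_cm1))) {
    stop("need lo_cm1 < center_cm1 < hi_cm1 for every band", call. = FALSE)
  }
  structure(data.frame(label = as.character(label), center_cm1 = center_cm1,
                       lo_cm1 = lo_cm1, hi_cm1 = hi_cm1,
                       assignment = rep_len(assignment, length(label))),
            class = c("band_table_def", "data.frame"))
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  band_definition(
    label = c("2924", "1549", "1452", "1313", "1120", "836"),
    center_cm1 = c(2924, 1549, 1452, 1313, 1120, 836),
    lo_cm1 = c(2874, 1506, 1425, 1280, 1087, 815),
    hi_cm1 = c(2974, 1592, 1482, 1346, 1153, 860),
    assignment = c(
      "asymmetric CH2 stretch of lipid acyl chains",
      "amide II",
      "asymmetric CH3 bending of protein methyl groups",
      "amide III",
      "mannose-6-phosphate / phosphorylated saccharide",
      "C2 endo/anti sugar conformation"))
}

#' Integrate a band area
#'
#' Trapezoidal integral of the absorbance over the band window (in cm^-1),
#' after subtracting the local linear baseline through the window's endpoint
#' absorbances (the OPUS "integration method B" style, robust to residual
#' drift). The result may be negative and is reported as-is. The operation
#' is linear in the spectrum.
#'
#' @param s A preprocessed [ftir_spectrum()].
#' @param lo_cm1,hi_cm1 Window bounds; must contain at least 3 grid points.
#' @return The band area in absorbance x cm^-1.
#' @examples
#' wn <- seq(1600, 1300, by = -4)
#' s <- ftir_spectrum(wn, exp(-0.5 * ((wn - 1452) / 10)^2), "gauss")
#' integrate_band(s, 1402, 1502) # ~ 10 * sqrt(2 * pi)
#' @export
integrate_band <- function(s, lo_cm1, hi_cm1) {
  stopifnot(is_spectrum(s), lo_cm1 < hi_cm1)
  x <- rev(s$wavenumber)
  y <- rev(s$absorbance)
  idx <- which(x >= lo_cm1 & x <= hi_cm1)
  if (length(idx) < 3) {
    stop("sample '", s$sample_id, "': window [", lo_cm1, ", ", hi_cm1,
         "] covers fewer than 3 grid points", call. = FALSE)
  }
  xs <- x[idx]
  ys <- y[idx]
  m <- length(xs)
  chord <- ys[1] + (ys[m] - ys[1]) * (xs - xs[1]) / (xs[m] - xs[1])
  pracma::trapz(xs, ys - chord)
}

#' Band-area table for a cohort
#'
#' Preprocesses every spectrum (baseline correction then vector
#' normalization; no derivative) and integrates every band. Because
#' normalization removes per-sample gain, the table is invariant to
#' rescaling individual spectra.
#'
#' @param cohort An [ftir_cohort()].
#' @param bands A [band_definition()] table.
#' @param config A [preprocess_config()].
#' @return A data frame of class `band_area_table`: columns `sample_id`,
#'   `group`, `glycemia_mgdl` and one `area_<label>` column per band.
#' @export
band_table <- function(cohort, bands = default_bands(),
                       config = preprocess_config()) {
  stopifnot(inherits(cohort, "ftir_cohort"),
            inherits(bands, "band_table_def"))
  areas <- vapply(cohort$spectra, function(s) {
    p <- tryCatch({
      s2 <- baseline_correct(s, config$baseline)
      vector_normalize(s2, config$normalization)
    }, error = function(e) {
      stop("sample '", s$sample_id, "': ", conditionMessage(e),
           call. = FALSE)
    })
    vapply(seq_len(nrow(bands)), function(i) {
      integrate_band(p, bands$lo_cm1[i], bands$hi_cm1[i])
    }, numeric(1))
  }, numeric(nrow(bands)))
  areas <- if (nrow(bands) == 1) matrix(areas, ncol = 1) else t(areas)
  colnames(areas) <- paste0("area_", bands$label)
  out <- cbind(cohort$records, as.data.frame(areas))
  rownames(out) <- NULL
  class(out) <- c("band_area_table", "data.frame")
  out
}

area_column <- function(table, band_label) {
  col <- paste0("area_", band_label)
  if (!col %in% names(table)) {
    stop("no band '", band_label, "' in table (have: ",
         paste(sub("^area_", "", grep("^area_", names(table), value = TRUE)),
               collapse = ", "), ")", call. = FALSE)
  }
  table[[col]]
}

#' Group comparison of one band's areas
#'
#' One-way ANOVA across the three groups followed by Tukey HSD pairwise
#' comparisons (the Tukey-Kramer adjustment handles the unbalanced group
#' sizes), with a Kolmogorov-Smirnov normality check per group. Normality
#' failures are reported, not acted on — the analysis stays parametric
#' throughout. If the within-group variance is numerically zero while the
#' group means differ, the F statistic degenerates; this is reported as
#' `p = 0` with `degenerate = TRUE`.
#'
#' @param table A [band_table()] result.
#' @param band_label Band to compare, e.g. `"1452"`.
#' @return A list of class `group_comparison` with per-group `mean`/`sd`/`n`,
#'   `anova_F`, `anova_p`, `tukey` (matrix of pairwise results), `ks_p`
#'   (per-group normality p-values) and `degenerate`.
#' @export
compare_groups <- function(table, band_label) {
  area <- area_column(table, band_label)
  group <- as_group(table$group)
  n <- tapply(area, group, length)
  if (sum(!is.na(n) & n >= 2) < 2 || any(n[!is.na(n)] < 2)) {
    stop("every group present must have >= 2 samples", call. = FALSE)
  }
  keep <- !is.na(n)
  mu <- tapply(area, group, mean)[keep]
  sd_g <- tapply(area, group, stats::sd)[keep]
  df <- data.frame(area = area, group = droplevels(group))
  ss_within <- sum(tapply(area, df$group,
                          function(v) sum((v - mean(v))^2)))
  ss_between <- sum(tapply(area, df$group,
                           function(v) length(v) * (mean(v) - mean(area))^2))
  degenerate <- ss_within <= 1e-24 * max(ss_between, 1e-300)
  if (degenerate && ss_between > 0) {
    k <- nlevels(df$group)
    tuk_levels <- utils::combn(levels(df$group), 2)
    tukey <- matrix(0, ncol(tuk_levels), 4,
                    dimnames = list(paste(tuk_levels[2, ], tuk_levels[1, ],
                                          sep = "-"),
                                    c("diff", "lwr", "upr", "p adj")))
    tukey[, "diff"] <- apply(tuk_levels, 2,
                             function(p) mu[[p[2]]] - mu[[p[1]]])
    res <- list(F = Inf, p = 0, tukey = tukey)
  } else {
    fit <- stats::aov(area ~ group, data = df)
    an <- summary(fit)[[1]]
    res <- list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                tukey = stats::TukeyHSD(fit)$group)
  }
  ks_p <- vapply(levels(df$group), function(g) {
    v <- area[df$group == g]
    if (stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(
      stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
  }, numeric(1))
  structure(list(band = band_label, n = n[keep], mean = mu, sd = sd_g,
                 anova_F = res$F, anova_p = res$p, tukey = res$tukey,
                 ks_p = ks_p, degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Band ", x$band, " cm^-1: ANOVA F = ", format(x$anova_F, digits = 4),
      ", p = ", format.pval(x$anova_p, digits = 3),
      if (x$degenerate) " (degenerate within-group variance)", "\n",
      sep = "")
  for (g in names(x$mean)) {
    cat(sprintf("  %-4s n=%d  mean=%.5g  sd=%.3g  KS p=%s\n", g, x$n[[g]],
                x$mean[[g]], x$sd[[g]], format.pval(x$ks_p[[g]],
                                                    digits = 3)))
  }
  cat("  Tukey adjusted p-values:\n")
  for (i in seq_len(nrow(x$tukey))) {
    cat(sprintf("    %-10s p=%s\n", rownames(x$tukey)[i],
                format.pval(x$tukey[i, "p adj"], digits = 3)))
  }
  invisible(x)
}

#' Pearson correlation between a band area and glycemia
#'
#' @param table A [band_table()] result (needs `glycemia_mgdl`).
#' @param band_label Band label.
#' @return A list with `r`, `p` (two-sided, t distribution on n-2 df) and
#'   `n`.
#' @export
glycemia_correlation <- function(table, band_label) {
  area <- area_column(table, band_label)
  gly <- table$glycemia_mgdl
  if (length(area) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(area) == 0 || stats::sd(gly) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(area, gly, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(area))
}
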