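#' Full-pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic-cohort generator, the
#' preprocessing choices, the band table, the clustering regions, the ROC
#' comparisons, and the component count for PCA-LDA. A single master seed
#' governs all stochastic stages; no stage draws from global randomness.
#'
#' @param cohort A [cohort_config()].
#' @param preprocess A [preprocess_config()].
#' @param bands A [band_definition()] table.
#' @param regions A [region_set()].
#' @param comparisons ROC comparisons to run.
#' @param n_pcs Components retained in PCA-LDA.
#' @param hca_k Clusters to cut in HCA.
#' @param seed Optional override of `cohort$seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            preprocess = preprocess_config(),
                            bands = default_bands(),
                            regions = default_regions(),
                            comparisons = c("normo_vs_D", "DI_vs_D"),
                            n_pcs = 6L, hca_k = 3L, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(preprocess, "preprocess_config"),
            inherits(bands, "band_table_def"),
            inherits(regions, "region_set"),
            all(comparisons %in% c("normo_vs_D", "DI_vs_D")))
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, preprocess = preprocess, bands = bands,
                 regions = regions, comparisons = comparisons,
                 n_pcs = as.integer(n_pcs), hca_k = as.integer(hca_k)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or inside any section) are rejected, so a
#' typo in a config file fails loudly instead of silently using a default.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "preprocess", "bands", "regions", "comparisons",
             "n_pcs", "hca_k", "seed")
  check_keys(raw, known, "top level")
  cohort <- cohort_config()
  if (!is.null(raw$cohort)) {
    cc <- raw$cohort
    check_keys(cc, c("n_per_group", "grid_hi", "grid_lo", "grid_step",
                     "bands", "glycemia", "baseline_order",
                     "baseline_scale", "scatter_sd", "noise_sd", "seed",
                     "effect_scale"), "cohort")
    bands <- if (!is.null(cc$bands)) {
      lapply(cc$bands, function(b) {
        check_keys(b, c("label", "center_cm1", "width_cm1", "amplitude",
                        "group_scale", "glycemia_slope", "shape"),
                   "cohort band")
        do.call(band_spec, utils::modifyList(
          list(label = b$label, center_cm1 = b$center_cm1,
               width_cm1 = b$width_cm1, amplitude = b$amplitude),
          b[intersect(names(b), c("group_scale", "glycemia_slope",
                                  "shape"))]))
      })
    } else {
      default_band_specs(if (is.null(cc$effect_scale)) 1 else
        cc$effect_scale)
    }
    glycemia <- if (!is.null(cc$glycemia)) {
      check_keys(cc$glycemia, c("mean", "sd"), "glycemia")
      glycemia_model(mean = unlist(cc$glycemia$mean),
                     sd = unlist(cc$glycemia$sd))
    } else glycemia_model()
    args <- list(bands = bands, glycemia = glycemia)
    for (key in c("n_per_group", "grid_hi", "grid_lo", "grid_step",
                  "baseline_order", "baseline_scale", "scatter_sd",
                  "noise_sd", "seed")) {
      if (!is.null(cc[[key]])) {
        args[[key]] <- if (key == "n_per_group") unlist(cc[[key]]) else
          cc[[key]]
      }
    }
    cohort <- do.call(cohort_config, args)
  }
  preprocess <- if (!is.null(raw$preprocess)) {
    check_keys(raw$preprocess, c("baseline", "normalization", "sg_window",
                                 "sg_polyorder"), "preprocess")
    do.call(preprocess_config, raw$preprocess)
  } else preprocess_config()
  bands <- if (!is.null(raw$bands)) {
    bl <- raw$bands
    band_definition(
      label = vapply(bl, `[[`, character(1), "label"),
      center_cm1 = vapply(bl, `[[`, numeric(1), "center_cm1"),
      lo_cm1 = vapply(bl, `[[`, numeric(1), "lo_cm1"),
      hi_cm1 = vapply(bl, `[[`, numeric(1), "hi_cm1"))
  } else default_bands()
  regions <- if (!is.null(raw$regions)) {
    rl <- raw$regions
    region_set(labels = vapply(rl, `[[`, character(1), "label"),
               hi_cm1 = vapply(rl, `[[`, numeric(1), "hi_cm1"),
               lo_cm1 = vapply(rl, `[[`, numeric(1), "lo_cm1"))
  } else default_regions()
  pipeline_config(
    cohort = cohort, preprocess = preprocess, bands = bands,
    regions = regions,
    comparisons = if (!is.null(raw$comparisons)) unlist(raw$comparisons)
      else c("normo_vs_D", "DI_vs_D"),
    n_pcs = if (!is.null(raw$n_pcs)) raw$n_pcs else 6L,
    hca_k = if (!is.null(raw$hca_k)) raw$hca_k else 3L,
    seed = raw$seed)
}

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic YAML snapshot of a pipeline config (used for the manifest)
write_config_snapshot <- function(config, path) {
  snap <- list(
    cohort = list(
      n_per_group = as.list(config$cohort$n_per_group),
      grid_hi = config$cohort$grid_hi, grid_lo = config$cohort$grid_lo,
      grid_step = config$cohort$grid_step,
      glycemia = list(mean = as.list(config$cohort$glycemia$mean),
                      sd = as.list(config$cohort$glycemia$sd)),
      bands = lapply(config$cohort$bands, function(b) {
        list(label = b$label, center_cm1 = b$center_cm1,
             width_cm1 = b$width_cm1, amplitude = b$amplitude,
             group_scale = as.list(b$group_scale),
             glycemia_slope = b$glycemia_slope, shape = b$shape)
      }),
      baseline_order = config$cohort$baseline_order,
      baseline_scale = config$cohort$baseline_scale,
      scatter_sd = config$cohort$scatter_sd,
      noise_sd = config$cohort$noise_sd,
      seed = config$cohort$seed),
    preprocess = unclass(config$preprocess),
    bands = lapply(seq_len(nrow(config$bands)), function(i) {
      as.list(config$bands[i, c("label", "center_cm1", "lo_cm1",
                                "hi_cm1")])
    }),
    regions = lapply(seq_len(nrow(config$regions)), function(i) {
      as.list(config$regions[i, ])
    }),
    comparisons = as.list(config$comparisons),
    n_pcs = config$n_pcs, hca_k = config$hca_k)
  yaml::write_yaml(snap, path, precision = 15)
  invisible(path)
}

write_table <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the complete analysis pipeline
#'
#' Executes, in order: cohort simulation, validation, preprocessing (group
#' mean and difference spectra), band-area quantification with group
#' statistics and glycemia correlations, ROC evaluation of every band under
#' every configured comparison, PCA-LDA with leave-one-out cross-validation,
#' and Ward HCA. All artifacts are written to `out` as plain CSV/JSON/YAML
#' and summarized in `manifest.json` (config hash, seed, package version,
#' per-file MD5 checksums). Re-running with an identical config and seed
#' reproduces every checksum, so the manifest doubles as a reproducibility
#' receipt. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out Output directory.
#' @param seed Optional seed override.
#' @param quiet Suppress per-stage progress messages?
#' @return The manifest, invisibly (a named list).
#' @export
run_all <- function(config = pipeline_config(), out, seed = NULL,
                    quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$cohort$seed <- as.integer(seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("stage simulate: ", sum(config$cohort$n_per_group),
      " samples, seed ", config$cohort$seed)
  cohort <- stage("simulate", {
    ch <- generate_cohort(config$cohort)
    write_cohort(ch, file.path(out, "cohort"))
    ch
  })

  say("stage validate")
  stage("validate", {
    diag <- validate_cohort_dir(file.path(out, "cohort"))
    if (any(!diag$ok)) {
      stop("invalid spectra: ",
           paste(diag$sample_id[!diag$ok], collapse = ", "))
    }
    write_table(diag, file.path(out, "validation.csv"))
  })

  say("stage preprocess: group means and differences")
  stage("preprocess", {
    means <- lapply(group_levels(), function(g) mean_spectrum(cohort, g))
    names(means) <- group_levels()
    df <- data.frame(wavenumber_cm1 = cohort$grid)
    for (g in group_levels()) df[[paste0("mean_", g)]] <-
      means[[g]]$absorbance
    df$diff_D_minus_ND <-
      difference_spectrum(means[["D"]], means[["ND"]])$absorbance
    df$diff_DI_minus_ND <-
      difference_spectrum(means[["D+I"]], means[["ND"]])$absorbance
    write_table(df, file.path(out, "mean_spectra.csv"))
  })

  say("stage bands: ", nrow(config$bands), " bands")
  tab <- stage("bands", {
    tab <- band_table(cohort, config$bands, config$preprocess)
    write_table(tab, file.path(out, "band_areas.csv"))
    stats_rows <- lapply(config$bands$label, function(b) {
      cmp <- compare_groups(tab, b)
      cor <- glycemia_correlation(tab, b)
      data.frame(band = b,
                 mean_ND = cmp$mean[["ND"]], sd_ND = cmp$sd[["ND"]],
                 mean_D = cmp$mean[["D"]], sd_D = cmp$sd[["D"]],
                 mean_DI = cmp$mean[["D+I"]], sd_DI = cmp$sd[["D+I"]],
                 anova_F = cmp$anova_F, anova_p = cmp$anova_p,
                 tukey_p_D_vs_ND = cmp$tukey["D-ND", "p adj"],
                 tukey_p_DI_vs_ND = cmp$tukey["D+I-ND", "p adj"],
                 tukey_p_DI_vs_D = cmp$tukey["D+I-D", "p adj"],
                 pearson_r = cor$r, pearson_p = cor$p)
    })
    write_table(do.call(rbind, stats_rows),
                file.path(out, "band_stats.csv"))
    tab
  })

  say("stage roc: ", nrow(config$bands), " bands x ",
      length(config$comparisons), " comparisons")
  stage("roc", {
    cut_rows <- list()
    for (b in config$bands$label) {
      for (cmp in config$comparisons) {
        ev <- evaluate_band(tab, b, cmp)
        write_table(ev$roc$points,
                    file.path(out, sprintf("roc_%s_%s.csv", b, cmp)))
        cut_rows[[paste(b, cmp)]] <- data.frame(
          band = b, comparison = cmp, auc = ev$roc$auc,
          p_value = ev$roc$p_value, cutoff = ev$cutoff$cutoff,
          sensitivity_pct = ev$cutoff$sensitivity,
          specificity_pct = ev$cutoff$specificity,
          youden_j = ev$cutoff$youden_j)
      }
    }
    write_table(do.call(rbind, cut_rows), file.path(out, "cutoffs.csv"))
  })

  say("stage classify: PCA-LDA leave-one-out")
  stage("classify", {
    cv <- loocv_pca_lda(cohort, n_pcs = config$n_pcs,
                        config = config$preprocess)
    write_table(cv$predictions, file.path(out, "loocv_predictions.csv"))
    write_table(as.data.frame(cv$confusion),
                file.path(out, "confusion_pca_lda.csv"))
    pv <- data.frame(component = seq_along(cv$pca$prop_var),
                     prop_var = cv$pca$prop_var,
                     cum_prop_var = cumsum(cv$pca$prop_var))
    write_table(utils::head(pv, 20), file.path(out, "pca_variance.csv"))
    k <- min(config$n_pcs, ncol(cv$pca$scores))
    lda_full <- lda_fit(cv$pca$scores[, seq_len(k), drop = FALSE],
                        cohort$records$group)
    coefs <- as.data.frame(t(lda_full$coef))
    coefs <- cbind(class = lda_full$levels, coefs,
                   constant = lda_full$const)
    write_table(coefs, file.path(out, "lda_coefficients.csv"))
  })

  say("stage cluster: Ward HCA on ", nrow(config$regions), " regions")
  stage("cluster", {
    hc <- hca(cohort, config$regions, k = config$hca_k)
    write_table(data.frame(sample_id = cohort$records$sample_id,
                           group = cohort$records$group,
                           cluster = hc$cluster,
                           predicted = hc$mapping[hc$cluster]),
                file.path(out, "hca_assignments.csv"))
    write_table(as.data.frame(hc$confusion),
                file.path(out, "confusion_hca.csv"))
    export_dendrogram(hc, file.path(out, "dendrogram.json"), "json")
  })

  say("stage manifest")
  manifest <- stage("manifest", {
    snap_path <- file.path(out, "config.yaml")
    write_config_snapshot(config, snap_path)
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          "manifest.json"))
    sums <- tools::md5sum(file.path(out, files))
    names(sums) <- files
    m <- list(package = "salivaftir",
              version = as.character(utils::packageVersion("salivaftir")),
              seed = config$cohort$seed,
              config_hash = unname(tools::md5sum(snap_path)),
              n_samples = sum(config$cohort$n_per_group),
              checksums = as.list(sums))
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Tabulates, from the artifact directory, the glycemia group statistics,
#' the per-band ANOVA/Tukey results and glycemia correlations, one ROC block
#' per band and comparison, and the PCA-LDA and HCA confusion matrices and
#' accuracies.
#'
#' @param dir Artifact directory produced by [run_all()].
#' @return A character vector of report lines (class `ftir_report`; its
#'   print method cats them).
#' @export
report <- function(dir) {
  need <- c(cohort = "cohort/metadata.csv", bands = "band_stats.csv",
            roc = "cutoffs.csv", classify = "confusion_pca_lda.csv",
            cluster = "confusion_hca.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop("incomplete run: missing stage artifact(s): ",
         paste(names(missing), collapse = ", "), call. = FALSE)
  }
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  meta <- utils::read.csv(file.path(dir, "cohort", "metadata.csv"))
  add("=== Salivary ATR-FTIR pipeline report ===")
  add(sprintf("Samples: %d (%s)", nrow(meta),
              paste(names(table(meta$group)), table(meta$group),
                    sep = "=", collapse = ", ")))
  for (g in group_levels()) {
    v <- meta$glycemia_mgdl[meta$group == g]
    add(sprintf("  %-4s glycemia %.1f +/- %.1f mg/dL", g, mean(v),
                stats::sd(v)))
  }
  bs <- utils::read.csv(file.path(dir, "band_stats.csv"))
  add("", "--- Band areas (normalized absorbance x cm^-1) ---")
  for (i in seq_len(nrow(bs))) {
    add(sprintf("Band %s cm^-1: ANOVA p=%.3g; Tukey D-ND p=%.3g, D+I-ND p=%.3g; Pearson r=%.3f (p=%.3g)",
                bs$band[i], bs$anova_p[i], bs$tukey_p_D_vs_ND[i],
                bs$tukey_p_DI_vs_ND[i], bs$pearson_r[i], bs$pearson_p[i]))
  }
  cut <- utils::read.csv(file.path(dir, "cutoffs.csv"))
  add("", "--- ROC diagnostics (positive class: D) ---")
  for (i in seq_len(nrow(cut))) {
    add(sprintf("Band %s, %s: AUC=%.3f, cutoff=%.4g, sensitivity=%.2f%%, specificity=%.2f%%",
                cut$band[i], cut$comparison[i], cut$auc[i], cut$cutoff[i],
                cut$sensitivity_pct[i], cut$specificity_pct[i]))
  }
  conf_fmt <- function(path, title) {
    cf <- utils::read.csv(path)
    tb <- stats::xtabs(Freq ~ truth + predicted, data = cf)
    acc <- 100 * sum(diag(tb)) / sum(tb)
    add("", sprintf("--- %s: accuracy %.1f%% (%d/%d) ---", title, acc,
                    sum(diag(tb)), sum(tb)))
    add(utils::capture.output(print(tb)))
  }
  conf_fmt(file.path(dir, "confusion_pca_lda.csv"),
           "PCA-LDA leave-one-out")
  conf_fmt(file.path(dir, "confusion_hca.csv"), "Ward HCA")
  structure(ln, class = "ftir_report")
}

#' @export
print.ftir_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
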