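#' Principal component analysis of a spectral matrix
#'
#' Mean-centered PCA via eigendecomposition of the covariance matrix (the
#' dual Gram-matrix form is used when variables outnumber samples; the two
#' are algebraically identical). Components are sorted by decreasing
#' variance; variance proportions are relative to the *total* variance, so
#' retained proportions sum to at most 1.
#'
#' @param x Numeric matrix, samples in rows, spectral points in columns.
#' @return An object of class `ftir_pca`: `center` (mean spectrum),
#'   `loadings` (orthonormal columns), `sdev`, `prop_var`, `scores`.
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  total_var <- sum(xc^2) / (n - 1)
  if (ncol(x) <= n) {
    e <- eigen(stats::cov(x), symmetric = TRUE)
    keep <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 0)
    lam <- e$values[keep]
    v <- e$vectors[, keep, drop = FALSE]
  } else {
    g <- xc %*% t(xc) / (n - 1)
    e <- eigen(g, symmetric = TRUE)
    keep <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 0)
    lam <- e$values[keep]
    v <- t(xc) %*% e$vectors[, keep, drop = FALSE]
    v <- sweep(v, 2, sqrt(lam * (n - 1)), "/")
  }
  scores <- xc %*% v
  colnames(v) <- colnames(scores) <- paste0("PC", seq_along(lam))
  structure(list(center = ctr, loadings = v, sdev = sqrt(lam),
                 prop_var = lam / total_var, scores = scores),
            class = "ftir_pca")
}

#' @export
print.ftir_pca <- function(x, ...) {
  k <- min(6, length(x$sdev))
  cat("PCA: ", length(x$sdev), " components over ", nrow(x$loadings),
      " spectral points\n", sep = "")
  cat("  variance proportions:",
      paste0(sprintf("%.1f%%", 100 * x$prop_var[seq_len(k)]),
             collapse = ", "),
      if (length(x$sdev) > k) "...", "\n")
  invisible(x)
}

#' @export
predict.ftir_pca <- function(object, newdata, ...) {
  newdata <- rbind(newdata) # accept a bare vector
  sweep(as.matrix(newdata), 2, object$center) %*% object$loadings
}

#' Choose the number of principal components
#'
#' Smallest `k` whose cumulative variance proportion reaches
#' `target_cumvar`; alternatively a fixed `k` (capped at the number of
#' available components) to mirror analyses that always retain six PCs.
#'
#' @param model An `ftir_pca` object, or a numeric vector of variance
#'   proportions.
#' @param target_cumvar Target cumulative proportion in `(0, 1]`.
#' @param k Optional fixed component count overriding the target rule.
#' @return An integer component count.
#' @examples
#' select_pcs(c(0.390, 0.320, 0.113, 0.082, 0.031, 0.022, 0.015),
#'            target_cumvar = 0.958) # 6
#' @export
select_pcs <- function(model, target_cumvar = 0.958, k = NULL) {
  prop <- if (inherits(model, "ftir_pca")) model$prop_var else
    as.numeric(model)
  if (!is.null(k)) return(as.integer(min(k, length(prop))))
  stopifnot(target_cumvar > 0, target_cumvar <= 1)
  cs <- cumsum(prop)
  hit <- which(cs >= target_cumvar - 1e-9)
  if (length(hit) == 0) length(prop) else hit[1]
}

#' Linear discriminant analysis on component scores
#'
#' Classical LDA with a pooled within-class covariance; a small ridge term
#' (`lambda * trace / d` on the diagonal) is added when the pooled matrix is
#' ill-conditioned. Priors are equal by default — group sizes here are set
#' by experimental design, not prevalence — with proportional priors as an
#' option. Per-class linear discriminant functions
#' `x' S^-1 m_k - m_k' S^-1 m_k / 2 + log p_k` and Mahalanobis distances
#' under the pooled covariance are reported.
#'
#' @param x Numeric score matrix (samples x dimensions).
#' @param labels Class labels; at least 2 classes with 2 samples each.
#' @param prior `"equal"` or `"proportional"`.
#' @param lambda Ridge coefficient applied when ill-conditioned.
#' @return An object of class `ftir_lda` with `means`, `pooled_cov`,
#'   `coef`, `const`, `prior`, `levels`.
#' @export
lda_fit <- function(x, labels, prior = c("equal", "proportional"),
                    lambda = 1e-6) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  labels <- factor(labels)
  labels <- droplevels(labels)
  n <- nrow(x)
  d <- ncol(x)
  k <- nlevels(labels)
  if (k < 2) stop("LDA needs at least 2 classes", call. = FALSE)
  cnt <- table(labels)
  if (any(cnt < 2)) {
    stop("every class needs >= 2 samples (", names(cnt)[cnt < 2][1],
         " has ", min(cnt), ")", call. = FALSE)
  }
  if (n <= d) {
    warning("fewer samples than dimensions + 1; LDA may be unstable")
  }
  means <- do.call(rbind, lapply(levels(labels), function(g) {
    colMeans(x[labels == g, , drop = FALSE])
  }))
  rownames(means) <- levels(labels)
  sw <- matrix(0, d, d)
  for (g in levels(labels)) {
    xc <- sweep(x[labels == g, , drop = FALSE], 2, means[g, ])
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (n - k)
  ev <- eigen(sw, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10) {
    sw <- sw + diag(lambda * sum(diag(sw)) / d, d)
    ev <- eigen(sw, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("pooled covariance singular even after regularization",
           call. = FALSE)
    }
  }
  sinv <- solve(sw)
  p <- if (prior == "equal") rep(1 / k, k) else as.numeric(cnt) / n
  names(p) <- levels(labels)
  coef <- sinv %*% t(means) # d x k
  const <- vapply(seq_len(k), function(i) {
    -0.5 * drop(means[i, ] %*% sinv %*% means[i, ]) + log(p[i])
  }, numeric(1))
  names(const) <- levels(labels)
  structure(list(means = means, pooled_cov = sw, coef = coef,
                 const = const, prior = p, levels = levels(labels)),
            class = "ftir_lda")
}

#' @export
print.ftir_lda <- function(x, ...) {
  cat("LDA: ", length(x$levels), " classes (",
      paste(x$levels, collapse = ", "), ") in ", nrow(x$coef),
      " dimensions; priors ",
      paste(sprintf("%.2f", x$prior), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @describeIn lda_fit Predict classes for new score vectors. Returns a list
#'   with `class` (factor), `scores` (discriminant values) and `mahalanobis`
#'   (squared distances to each class mean under the pooled covariance).
#'   Exact score ties fall back to the first class in label order, with a
#'   warning.
#' @param object An `ftir_lda` model.
#' @param newdata Matrix (or single vector) of score coordinates.
#' @param ... Unused.
#' @export
predict.ftir_lda <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  sc <- as.matrix(newdata) %*% object$coef
  sc <- sweep(sc, 2, object$const, `+`)
  colnames(sc) <- object$levels
  tie <- apply(sc, 1, function(r) {
    sum(r >= max(r) - 1e-9 * max(1, abs(max(r)))) > 1
  })
  if (any(tie)) {
    warning("discriminant score tie; falling back to first class in ",
            "label order")
  }
  cls <- factor(object$levels[apply(sc, 1, which.max)],
                levels = object$levels)
  sinv <- solve(object$pooled_cov)
  maha <- t(apply(as.matrix(newdata), 1, function(v) {
    vapply(seq_along(object$levels), function(i) {
      d <- v - object$means[i, ]
      drop(d %*% sinv %*% d)
    }, numeric(1))
  }))
  colnames(maha) <- object$levels
  list(class = cls, scores = sc, mahalanobis = maha)
}

# spectral feature matrix for the multivariate pipeline: Savitzky-Golay
# second derivative, vector normalization, restriction to the analysis range
multivariate_features <- function(cohort, config = preprocess_config(),
                                  range_cm1 = c(3700, 500)) {
  lo <- min(range_cm1)
  hi <- max(range_cm1)
  feats <- lapply(cohort$spectra, function(s) {
    d2 <- second_derivative(s, config$sg_window, config$sg_polyorder)
    d2 <- vector_normalize(d2, "opus_vector")
    keep <- d2$wavenumber >= lo & d2$wavenumber <= hi
    d2$absorbance[keep]
  })
  m <- do.call(rbind, feats)
  rownames(m) <- cohort$records$sample_id
  m
}

#' PCA-LDA classification with leave-one-out cross-validation
#'
#' For every sample the full pipeline — Savitzky-Golay second derivative,
#' vector normalization, restriction to the 3700-500 cm^-1 range (or the
#' available grid), PCA, component selection, LDA — is refit on the
#' remaining n-1 samples and the held-out sample is predicted, so no
#' information leaks into the fold. Six components are retained when the
#' training set admits them (`n - 1 >= 7`), otherwise the maximum
#' available. `pca_refit = FALSE` fits the PCA once on all samples (for
#' comparability with single-decomposition workflows) while still
#' cross-validating the LDA.
#'
#' @param cohort An [ftir_cohort()] with at least 3 samples per class.
#' @param n_pcs Component count to retain per fold (capped by availability).
#' @param config A [preprocess_config()] (derivative parameters).
#' @param range_cm1 Analysis range, cm^-1.
#' @param pca_refit Refit the PCA inside every fold?
#' @param prior LDA priors, see [lda_fit()].
#' @return An object of class `ftir_loocv`: `predictions` (data frame with
#'   `sample_id`, `truth`, `predicted`, per-class Mahalanobis distances),
#'   `confusion` (true x predicted), `accuracy` (percent), `pca`
#'   (full-data PCA, for variance reporting), `n_pcs`.
#' @export
loocv_pca_lda <- function(cohort, n_pcs = 6L, config = preprocess_config(),
                          range_cm1 = c(3700, 500), pca_refit = TRUE,
                          prior = "equal") {
  stopifnot(inherits(cohort, "ftir_cohort"))
  truth <- as_group(cohort$records$group)
  truth <- droplevels(truth)
  if (any(table(truth) < 3)) {
    stop("leave-one-out needs >= 3 samples per class", call. = FALSE)
  }
  feats <- multivariate_features(cohort, config, range_cm1)
  n <- nrow(feats)
  full_pca <- pca_fit(feats)
  pred <- character(n)
  maha <- matrix(NA_real_, n, nlevels(truth),
                 dimnames = list(NULL, levels(truth)))
  for (i in seq_len(n)) {
    res <- tryCatch({
      train <- feats[-i, , drop = FALSE]
      pca <- if (pca_refit) pca_fit(train) else full_pca
      kk <- if (n - 1 >= 7) min(n_pcs, ncol(pca$loadings)) else
        ncol(pca$loadings)
      tr_scores <- predict(pca, train)[, seq_len(kk), drop = FALSE]
      lda <- lda_fit(tr_scores, truth[-i], prior = prior)
      te_scores <- predict(pca, feats[i, ])[, seq_len(kk), drop = FALSE]
      predict(lda, te_scores)
    }, error = function(e) {
      stop("LOOCV fold ", i, " (sample '", cohort$records$sample_id[i],
           "'): ", conditionMessage(e), call. = FALSE)
    })
    pred[i] <- as.character(res$class)
    maha[i, colnames(res$mahalanobis)] <- res$mahalanobis[1, ]
  }
  pred <- factor(pred, levels = levels(truth))
  confusion <- table(truth = truth, predicted = pred)
  acc <- 100 * sum(diag(confusion)) / n
  predictions <- data.frame(sample_id = cohort$records$sample_id,
                            truth = truth, predicted = pred)
  predictions <- cbind(predictions,
                       as.data.frame(maha) |>
                         stats::setNames(paste0("d2_", levels(truth))))
  structure(list(predictions = predictions, confusion = confusion,
                 accuracy = acc, pca = full_pca, n_pcs = n_pcs),
            class = "ftir_loocv")
}

#' @export
print.ftir_loocv <- function(x, ...) {
  cat(sprintf("PCA-LDA leave-one-out cross-validation: accuracy %.1f%% (%d/%d)\n",
              x$accuracy, sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}
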