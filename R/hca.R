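#' Ward hierarchical clustering on diagnostic spectral regions
#'
#' Per sample: the five diagnostic regions are extracted, each region slice
#' is vector normalized, the shared scaling-to-first-range map is applied
#' ([scale_to_first_range()]), and the concatenated vectors are clustered by
#' Ward's minimum-variance method on Euclidean distances. Merge heights are
#' reported as the Ward criterion — the increase in total within-cluster sum
#' of squares caused by each merge — and are non-decreasing. The tree is cut
#' at `k` clusters and clusters are mapped to groups by majority vote (ties
#' to the larger group, then label order), giving a confusion matrix and an
#' accuracy.
#'
#' @param cohort An [ftir_cohort()] with at least `k` samples.
#' @param regions A [region_set()].
#' @param k Number of clusters to cut (default 3, one per study group).
#' @return An object of class `ftir_hca`: `hclust` (the linkage tree),
#'   `height` (Ward merge costs), `cluster` (assignment at `k`), `mapping`
#'   (cluster to group), `confusion`, `accuracy` (percent), `features`.
#' @export
hca <- function(cohort, regions = default_regions(), k = 3L) {
  stopifnot(inherits(cohort, "ftir_cohort"))
  n <- nrow(cohort$records)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  feats <- hca_features(cohort, regions)
  d <- stats::dist(feats)
  hc <- stats::hclust(d^2, method = "ward.D")
  hc$height <- hc$height / 2 # ward.D on squared distances = 2 x delta-ESS
  cluster <- stats::cutree(hc, k = k)
  truth <- as_group(cohort$records$group)
  group_n <- table(truth)
  mapping <- vapply(seq_len(k), function(cl) {
    votes <- table(truth[cluster == cl])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) { # ties to the larger group, then label order
      top <- top[order(-as.numeric(group_n[top]),
                       match(top, group_levels()))]
    }
    top[1]
  }, character(1))
  predicted <- factor(mapping[cluster], levels = levels(truth))
  confusion <- table(truth = truth, predicted = predicted)
  acc <- 100 * sum(as.character(truth) == as.character(predicted)) / n
  structure(list(hclust = hc, height = hc$height, cluster = cluster,
                 mapping = mapping, confusion = confusion, accuracy = acc,
                 features = feats),
            class = "ftir_hca")
}

# per-sample region features: extract -> per-region vector normalize ->
# scale to first range -> concatenate
hca_features <- function(cohort, regions = default_regions()) {
  feats <- lapply(cohort$spectra, function(s) {
    scale_to_first_range(extract_regions(s, regions))$absorbance
  })
  m <- do.call(rbind, feats)
  rownames(m) <- cohort$records$sample_id
  m
}

#' @export
print.ftir_hca <- function(x, ...) {
  cat(sprintf("Ward HCA: %d samples, cut at k=%d, accuracy %.1f%% (%d/%d)\n",
              sum(x$confusion), length(x$mapping), x$accuracy,
              sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' @export
plot.ftir_hca <- function(x, ...) {
  graphics::plot(x$hclust, ylab = "Ward merge cost (delta ESS)", ...)
  invisible(x)
}

#' Export a dendrogram
#'
#' JSON export writes the nested merge tree with Ward merge heights;
#' Newick export uses \pkg{ape}.
#'
#' @param x An `ftir_hca` result.
#' @param path Output file.
#' @param format `"json"` or `"newick"`.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(x, path, format = c("json", "newick")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ftir_hca"))
  hc <- x$hclust
  if (format == "newick") {
    if (!requireNamespace("ape", quietly = TRUE)) {
      stop("Newick export needs the 'ape' package", call. = FALSE)
    }
    ape::write.tree(ape::as.phylo(hc), file = path)
  } else {
    node <- function(i) {
      if (i < 0) {
        list(label = hc$labels[-i])
      } else {
        list(height = hc$height[i],
             children = list(node(hc$merge[i, 1]), node(hc$merge[i, 2])))
      }
    }
    root <- node(nrow(hc$merge))
    jsonlite::write_json(root, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
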