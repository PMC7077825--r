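# Shared fixtures and independent oracles, built in code at test time.

# small, fast default-structure cohort config
tiny_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, ...)
}

# noise-free, baseline-free config with a single Gaussian band
clean_single_band_config <- function(center = 1452, width = 10,
                                     amplitude = 1, seed = 1, ...) {
  cohort_config(bands = list(band_spec("b", center, width, amplitude)),
                baseline_scale = 0, scatter_sd = 0, noise_sd = 0,
                seed = seed, ...)
}

# brute-force band-area oracle: trapezoid at 0.1 cm^-1 on a continuous
# absorbance function, local endpoint-chord baseline subtracted
riemann_band_area <- function(f, lo, hi, step = 0.1) {
  x <- seq(lo, hi, by = step)
  y <- f(x)
  m <- length(x)
  chord <- y[1] + (y[m] - y[1]) * (x - x[1]) / (x[m] - x[1])
  g <- y - chord
  sum((g[-1] + g[-m]) / 2 * diff(x))
}

# rank-statistic AUC oracle: P(pos more extreme than neg), ties half credit
mann_whitney_auc <- function(scores, pos, direction = "lower") {
  sp <- scores[pos]
  sn <- scores[!pos]
  cmp <- if (direction == "lower") outer(sp, sn, "<") else outer(sp, sn, ">")
  (sum(cmp) + 0.5 * sum(outer(sp, sn, "=="))) / (length(sp) * length(sn))
}

# exhaustive Ward agglomeration oracle: at each step merge the pair of
# clusters whose union minimizes the increase in within-cluster sum of
# squares; records merge costs and the partition after every merge
ward_bruteforce <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  partitions <- character(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]
        b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_cost)
    partitions <- c(partitions, partition_signature(clusters))
  }
  list(heights = heights, partitions = partitions)
}

partition_signature <- function(clusters) {
  sig <- sort(vapply(clusters, function(cl) {
    paste(sort(cl), collapse = ",")
  }, character(1)))
  paste(sig, collapse = "|")
}

# partition sequence implied by an hclust merge matrix
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  members <- lapply(seq_len(n), identity)
  clusters <- lapply(seq_len(n), identity)
  out <- character(0)
  node <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(k) if (k < 0) -k else NULL
    left <- hc$merge[i, 1]
    right <- hc$merge[i, 2]
    lm <- if (left < 0) -left else node[[left]]
    rm <- if (right < 0) -right else node[[right]]
    node[[i]] <- sort(c(lm, rm))
    drop <- vapply(clusters, function(cl) {
      all(cl %in% node[[i]])
    }, logical(1))
    clusters <- c(clusters[!drop], list(node[[i]]))
    out <- c(out, partition_signature(clusters))
  }
  out
}
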