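#' Preprocessing configuration
#'
#' Bundles the spectral conditioning choices applied before band integration
#' and multivariate analysis: baseline method, normalization mode and the
#' Savitzky-Golay derivative parameters. Defaults follow common ATR-FTIR
#' practice at 4 cm^-1 resolution: rubber-band baseline, OPUS-style vector
#' normalization, 9-point window, polynomial order 3.
#'
#' @param baseline `"rubberband"`, `"linear"` or `"none"`.
#' @param normalization `"opus_vector"`, `"unit_norm"` or `"none"`.
#' @param sg_window Savitzky-Golay window length in points; odd and greater
#'   than `sg_polyorder`.
#' @param sg_polyorder Savitzky-Golay polynomial order, `>= 2`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline = c("rubberband", "linear", "none"),
                              normalization = c("opus_vector", "unit_norm",
                                                "none"),
                              sg_window = 9L, sg_polyorder = 3L) {
  baseline <- match.arg(baseline)
  normalization <- match.arg(normalization)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder ||
      sg_polyorder < 2L) {
    stop("need odd sg_window > sg_polyorder >= 2", call. = FALSE)
  }
  structure(list(baseline = baseline, normalization = normalization,
                 sg_window = sg_window, sg_polyorder = sg_polyorder),
            class = "preprocess_config")
}

# indices of the lower convex hull (Andrew monotone chain), x ascending
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      # drop b if it lies on or above segment a--i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Baseline correction
#'
#' `"rubberband"` subtracts the lower convex hull of the (wavenumber,
#' absorbance) points — the standard rubber-band correction for ATR-FTIR
#' biofluid spectra; the corrected spectrum is non-negative and the
#' operation is idempotent. `"linear"` subtracts the chord between the first
#' and last points. `"none"` is the identity. A constant (or purely linear)
#' spectrum maps to all zeros under rubber-band correction.
#'
#' @param s An [ftir_spectrum()] with at least 3 points.
#' @param method Baseline method.
#' @return The corrected spectrum (grid and `sample_id` preserved).
#' @export
baseline_correct <- function(s, method = c("rubberband", "linear", "none")) {
  method <- match.arg(method)
  stopifnot(is_spectrum(s))
  if (method == "none") return(s)
  if (length(s$wavenumber) < 3) {
    stop("sample '", s$sample_id, "': need at least 3 points", call. = FALSE)
  }
  x <- rev(s$wavenumber) # ascending
  y <- rev(s$absorbance)
  if (method == "linear") {
    n <- length(x)
    base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
    out <- y - base
  } else {
    h <- lower_hull_idx(x, y)
    base <- stats::approx(x[h], y[h], xout = x, method = "linear",
                          ties = "ordered")$y
    out <- y - base
    out[out < 0] <- 0 # floating dust; exact hull is a lower bound
  }
  ftir_spectrum(x, out, s$sample_id)
}

#' Vector normalization
#'
#' `"opus_vector"` reproduces the OPUS convention: the mean absorbance is
#' subtracted, then the spectrum is divided by the Euclidean norm of the
#' centered vector, so the output has mean 0 and norm 1. `"unit_norm"`
#' divides by the Euclidean norm without centering. Either mode removes
#' per-sample gain, which makes downstream band areas and classifications
#' invariant to sample-to-sample intensity scaling.
#'
#' @param s An [ftir_spectrum()].
#' @param mode Normalization mode.
#' @return The normalized spectrum.
#' @export
vector_normalize <- function(s, mode = c("opus_vector", "unit_norm",
                                         "none")) {
  mode <- match.arg(mode)
  stopifnot(is_spectrum(s))
  if (mode == "none") return(s)
  y <- s$absorbance
  if (mode == "opus_vector") y <- y - mean(y)
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) {
    stop("sample '", s$sample_id, "': zero norm, cannot vector-normalize",
         call. = FALSE)
  }
  ftir_spectrum(s$wavenumber, y / nrm, s$sample_id)
}

#' Savitzky-Golay second derivative
#'
#' Second derivative with respect to grid index (on the constant-step grids
#' used throughout, this is proportional to the derivative in cm^-1).
#' Boundary points are handled by the Savitzky-Golay projection-matrix rows,
#' i.e. by polynomial fits at the edges, so the output has the input's
#' length.
#'
#' @param s An [ftir_spectrum()].
#' @param sg_window Odd window length in points, `<=` spectrum length.
#' @param sg_polyorder Polynomial order, `>= 2` and `< sg_window`.
#' @return The derivative spectrum.
#' @export
second_derivative <- function(s, sg_window = 9L, sg_polyorder = 3L) {
  stopifnot(is_spectrum(s))
  if (sg_window %% 2L == 0L) {
    stop("sg_window must be odd", call. = FALSE)
  }
  if (sg_window > length(s$wavenumber)) {
    stop("sample '", s$sample_id, "': window (", sg_window,
         ") exceeds spectrum length", call. = FALSE)
  }
  if (sg_polyorder < 2L || sg_polyorder >= sg_window) {
    stop("need 2 <= sg_polyorder < sg_window", call. = FALSE)
  }
  d2 <- signal::sgolayfilt(s$absorbance, p = sg_polyorder, n = sg_window,
                           m = 2, ts = 1)
  ftir_spectrum(s$wavenumber, d2, s$sample_id)
}

#' Mean spectrum of a cohort subset
#'
#' @param cohort An [ftir_cohort()] or a list of spectra on one grid.
#' @param group Optional group label to subset by (`NULL` = all samples).
#' @return The pointwise mean as an [ftir_spectrum()].
#' @export
mean_spectrum <- function(cohort, group = NULL) {
  spectra <- if (inherits(cohort, "ftir_cohort")) {
    if (is.null(group)) {
      cohort$spectra
    } else {
      cohort$spectra[as.character(cohort$records$group) %in% group]
    }
  } else cohort
  if (length(spectra) == 0) {
    stop("empty subset: no spectra to average", call. = FALSE)
  }
  m <- rowMeans(do.call(cbind, lapply(spectra, `[[`, "absorbance")))
  id <- if (is.null(group)) "mean" else paste0("mean_", group)
  ftir_spectrum(spectra[[1]]$wavenumber, m, id)
}

#' Pointwise difference of two spectra
#'
#' @param a,b Spectra on the same grid.
#' @return `a - b` as an [ftir_spectrum()].
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(is_spectrum(a), is_spectrum(b))
  if (length(a$wavenumber) != length(b$wavenumber) ||
      any(abs(a$wavenumber - b$wavenumber) > 1e-9)) {
    stop("spectra are not on the same grid", call. = FALSE)
  }
  ftir_spectrum(a$wavenumber, a$absorbance - b$absorbance,
                paste0(a$sample_id, "-", b$sample_id))
}

#' Diagnostic spectral regions for cluster analysis
#'
#' An ordered set of non-overlapping wavenumber windows. The defaults are
#' the five regions used for hierarchical clustering: A 2995-2889 (CH
#' stretches), B 1664-1581 (amide I/II edge), C 1410-1234 (CH bending /
#' amide III), D 1149-1080 (saccharide C-O) and E 1018-955 cm^-1.
#'
#' @param labels Region labels.
#' @param hi_cm1,lo_cm1 Upper and lower bounds per region; `hi > lo`.
#' @return A data frame of class `region_set` with columns `label`, `hi_cm1`,
#'   `lo_cm1`.
#' @export
region_set <- function(labels = c("A", "B", "C", "D", "E"),
                       hi_cm1 = c(2995, 1664, 1410, 1149, 1018),
                       lo_cm1 = c(2889, 1581, 1234, 1080, 955)) {
  stopifnot(length(labels) == length(hi_cm1),
            length(labels) == length(lo_cm1))
  if (length(labels) == 0) stop("empty region set", call. = FALSE)
  if (any(hi_cm1 <= lo_cm1)) {
    stop("each region needs hi_cm1 > lo_cm1", call. = FALSE)
  }
  o <- order(hi_cm1, decreasing = TRUE)
  if (any(lo_cm1[o][-length(o)] < hi_cm1[o][-1])) {
    stop("regions overlap", call. = FALSE)
  }
  structure(data.frame(label = as.character(labels), hi_cm1 = hi_cm1,
                       lo_cm1 = lo_cm1),
            class = c("region_set", "data.frame"))
}

#' @rdname region_set
#' @export
default_regions <- function() region_set()

#' Extract and concatenate spectral regions
#'
#' Slices the spectrum at each region in the listed order, preserving
#' descending wavenumber within each slice. A grid point on a region bound is
#' included when it lies within half a grid step of the bound.
#'
#' @param s An [ftir_spectrum()].
#' @param regions A [region_set()].
#' @return A list of class `ftir_regions` with elements `wavenumber`,
#'   `absorbance`, `region` (factor) and `sample_id`.
#' @export
extract_regions <- function(s, regions = default_regions()) {
  stopifnot(is_spectrum(s))
  if (!inherits(regions, "region_set") || nrow(regions) == 0) {
    stop("empty or invalid region set", call. = FALSE)
  }
  step <- grid_step(s)
  tol <- step / 2 + 1e-9
  wn_max <- max(s$wavenumber)
  wn_min <- min(s$wavenumber)
  parts <- lapply(seq_len(nrow(regions)), function(i) {
    hi <- regions$hi_cm1[i]
    lo <- regions$lo_cm1[i]
    if (hi > wn_max + tol || lo < wn_min - tol) {
      stop("region '", regions$label[i], "' [", lo, ", ", hi,
           "] outside the spectral grid", call. = FALSE)
    }
    idx <- which(s$wavenumber <= hi + tol & s$wavenumber >= lo - tol)
    if (length(idx) == 0) {
      stop("region '", regions$label[i], "' contains no grid points",
           call. = FALSE)
    }
    idx
  })
  idx <- unlist(parts)
  structure(list(wavenumber = s$wavenumber[idx],
                 absorbance = s$absorbance[idx],
                 region = factor(rep(regions$label,
                                     vapply(parts, length, integer(1))),
                                 levels = regions$label),
                 sample_id = s$sample_id),
            class = "ftir_regions")
}

#' Per-region normalization with scaling to the first range
#'
#' Reproduces the clustering preprocessing: each region slice is vector
#' normalized (mean 0, norm 1) independently, then one affine map — chosen
#' so that the *first* listed region's slice spans exactly `[0, 1]` — is
#' applied to all regions. The single shared map preserves the relative
#' scale between regions. This is this package's interpretation of the OPUS
#' "Scaling to 1st Range" option, whose exact algorithm is undocumented.
#'
#' @param r An `ftir_regions` object from [extract_regions()].
#' @return An `ftir_regions` object with transformed absorbances.
#' @export
scale_to_first_range <- function(r) {
  stopifnot(inherits(r, "ftir_regions"))
  y <- r$absorbance
  for (lev in levels(r$region)) {
    k <- r$region == lev
    v <- y[k] - mean(y[k])
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) {
      stop("sample '", r$sample_id, "': region '", lev,
           "' has zero norm", call. = FALSE)
    }
    y[k] <- v / nrm
  }
  first <- r$region == levels(r$region)[1]
  lo <- min(y[first])
  rng <- max(y[first]) - lo
  if (rng == 0) {
    stop("sample '", r$sample_id, "': first region has zero range",
         call. = FALSE)
  }
  r$absorbance <- (y - lo) / rng
  r
}
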