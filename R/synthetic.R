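#' Per-group glycemia distribution
#'
#' Group means and standard deviations of blood glucose (mg/dL). The defaults
#' are the study conditions of the emulated rat experiment: streptozotocin
#' diabetes raises fasting glycemia roughly six-fold and a 6 U/day insulin
#' regimen restores it to the non-diabetic level.
#'
#' @param mean,sd Named numeric vectors over `ND`, `D`, `D+I`; `sd` must be
#'   non-negative.
#' @return A list of class `glycemia_model`.
#' @export
glycemia_model <- function(mean = c("ND" = 83.2, "D" = 497.6, "D+I" = 81.0),
                           sd = c("ND" = 4.2, "D" = 19.6, "D+I" = 19.2)) {
  stopifnot(all(group_levels() %in% names(mean)),
            all(group_levels() %in% names(sd)))
  mean <- mean[group_levels()]
  sd <- sd[group_levels()]
  if (any(sd < 0)) stop("glycemia sd must be >= 0", call. = FALSE)
  if (any(mean <= 0)) stop("glycemia mean must be > 0", call. = FALSE)
  structure(list(mean = mean, sd = sd), class = "glycemia_model")
}

#' Draw glycemia values for one group
#'
#' Samples from a normal distribution truncated at zero (rejection sampling;
#' with the default means the truncation mass is negligible). With `sd = 0`
#' the group mean is returned exactly.
#'
#' @param group One of `"ND"`, `"D"`, `"D+I"`.
#' @param model A [glycemia_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is untouched.
#' @return Numeric vector of length `n`, all values `> 0`.
#' @export
sample_glycemia <- function(group, model = glycemia_model(), n = 1L,
                            seed = NULL) {
  stopifnot(inherits(model, "glycemia_model"))
  if (!is.character(group) || length(group) != 1L ||
      !group %in% group_levels()) {
    stop("unknown group label: '", paste(group, collapse = ","),
         "' (expected ND, D or D+I)", call. = FALSE)
  }
  m <- model$mean[[group]]
  s <- model$sd[[group]]
  draw <- function() {
    if (s == 0) return(rep(m, n))
    out <- stats::rnorm(n, m, s)
    while (any(out <= 0)) {
      k <- which(out <= 0)
      out[k] <- stats::rnorm(length(k), m, s)
    }
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Define one synthetic absorption band
#'
#' Bands are Gaussian by default (a Lorentzian profile is available); the
#' amplitude of band `b` for a sample in group `g` with glycemia `G` is
#' `group_scale[g] * (amplitude + glycemia_slope * (G - ref))`, floored at
#' zero, where `ref` is the non-diabetic mean glycemia. A negative
#' `glycemia_slope` therefore suppresses the band under hyperglycemia and
#' restores it under insulin treatment, and makes the band area negatively
#' correlated with glycemia across a cohort.
#'
#' @param label Band label (used in column names).
#' @param center_cm1 Band center, cm^-1.
#' @param width_cm1 Gaussian SD (or Lorentzian half-width), cm^-1, `> 0`.
#' @param amplitude Peak absorbance at the reference glycemia, `>= 0`.
#' @param group_scale Named multiplier per group.
#' @param glycemia_slope Amplitude change per mg/dL above the ND mean
#'   (absorbance units); `<= 0` for diagnostic bands.
#' @param shape `"gauss"` or `"lorentz"`.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(label, center_cm1, width_cm1, amplitude,
                      group_scale = c("ND" = 1, "D" = 1, "D+I" = 1),
                      glycemia_slope = 0, shape = c("gauss", "lorentz")) {
  shape <- match.arg(shape)
  stopifnot(width_cm1 > 0, amplitude >= 0,
            all(group_levels() %in% names(group_scale)))
  structure(list(label = as.character(label), center_cm1 = center_cm1,
                 width_cm1 = width_cm1, amplitude = amplitude,
                 group_scale = group_scale[group_levels()],
                 glycemia_slope = glycemia_slope, shape = shape),
            class = "band_spec")
}

band_profile <- function(band, wn) {
  z <- (wn - band$center_cm1) / band$width_cm1
  switch(band$shape,
         gauss = exp(-0.5 * z^2),
         lorentz = 1 / (1 + z^2))
}

#' Default synthetic band set
#'
#' Six diagnostic bands at the canonical saliva assignments — 2924 (lipid
#' CH2 asymmetric stretch), 1549 (amide II), 1452 (protein CH3 asymmetric
#' bending), 1313 (amide III), 1120 (phosphorylated saccharide) and 836 cm^-1
#' (C2 sugar conformation) — all coupled to glycemia with a negative slope,
#' the 1452 and 836 bands most strongly. Non-diagnostic filler bands (amide
#' I near 1652 cm^-1, C-O stretches near 1040 cm^-1, and others) carry no
#' group information, so classifiers cannot succeed from trivial global
#' intensity.
#'
#' Besides the glycemia coupling, the secretory signature of the disease and
#' of insulin treatment is emulated on three protein/saccharide bands whose
#' group scales differ for D and D+I — without it, insulin-treated animals
#' would be spectrally indistinguishable from non-diabetic ones and the
#' three-group classification the study design assumes could not exist. The
#' six diagnostic band areas remain ~ equal between ND and D+I.
#'
#' @param effect_scale Multiplier applied to every diagnostic band's
#'   `glycemia_slope` and to the deviation of every group scale from 1;
#'   `1` is the default study condition, larger values give stronger group
#'   separation.
#' @return A list of [band_spec()] objects.
#' @export
default_band_specs <- function(effect_scale = 1) {
  e <- effect_scale
  sc <- function(nd, d, di) { # amplify deviations from unity
    pmax(c("ND" = 1 + e * (nd - 1), "D" = 1 + e * (d - 1),
           "D+I" = 1 + e * (di - 1)), 0)
  }
  list(
    # diagnostic bands (negative glycemia coupling)
    band_spec("2924", 2924, 18, 0.28, glycemia_slope = -6.0e-5 * e),
    band_spec("1549", 1549, 16, 0.45, glycemia_slope = -8.0e-5 * e),
    band_spec("1452", 1452, 9, 0.30, glycemia_slope = -1.8e-4 * e),
    band_spec("1313", 1313, 11, 0.20, glycemia_slope = -5.0e-5 * e),
    band_spec("1120", 1120, 12, 0.22, glycemia_slope = -6.0e-5 * e),
    band_spec("836", 836, 9, 0.14, glycemia_slope = -1.0e-4 * e),
    # disease/treatment secretory signature on non-diagnostic bands
    band_spec("amideI", 1652, 25, 0.65, group_scale = sc(1, 0.94, 1.06)),
    band_spec("f1400", 1400, 12, 0.18, group_scale = sc(1, 1.00, 0.82)),
    band_spec("f1240", 1240, 15, 0.16, group_scale = sc(1, 1.12, 1.25)),
    # filler bands, identical in every group
    band_spec("chstretch", 2960, 20, 0.20),
    band_spec("f1040", 1040, 20, 0.35),
    band_spec("f900", 900, 15, 0.08),
    band_spec("f700", 700, 30, 0.10)
  )
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions for [generate_cohort()]: group sizes (8/6/7
#' as in the emulated study), the 3000-400 cm^-1 grid at 4 cm^-1 steps, the
#' band set, and the noise model (random smooth polynomial baseline,
#' multiplicative scatter on the chemical signal, additive white noise).
#'
#' @param n_per_group Named integer vector of samples per group.
#' @param grid_hi,grid_lo,grid_step Wavenumber grid bounds and step, cm^-1.
#' @param bands List of [band_spec()] objects.
#' @param glycemia A [glycemia_model()].
#' @param baseline_order Polynomial order of the random baseline drift.
#' @param baseline_scale SD of the baseline polynomial coefficients
#'   (absorbance units); 0 disables drift.
#' @param scatter_sd SD of the multiplicative gain applied to the band
#'   signal (unitless); 0 disables scatter.
#' @param noise_sd SD of the additive white noise (absorbance units).
#' @param seed Master integer seed; per-sample RNG substreams are derived
#'   from it by hashing `sample_id`, so enlarging a cohort never perturbs
#'   existing samples.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c("ND" = 8L, "D" = 6L, "D+I" = 7L),
                          grid_hi = 3000, grid_lo = 400, grid_step = 4,
                          bands = default_band_specs(),
                          glycemia = glycemia_model(),
                          baseline_order = 3L, baseline_scale = 0.01,
                          scatter_sd = 0.05, noise_sd = 0.004,
                          seed = 1L) {
  stopifnot(all(group_levels() %in% names(n_per_group)),
            grid_hi > grid_lo, grid_step > 0,
            baseline_order >= 0, baseline_scale >= 0,
            scatter_sd >= 0, noise_sd >= 0,
            inherits(glycemia, "glycemia_model"))
  n_per_group <- n_per_group[group_levels()]
  if (any(n_per_group <= 0)) {
    stop("n_per_group must be positive for every group", call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, grid_hi = grid_hi,
                 grid_lo = grid_lo, grid_step = grid_step, bands = bands,
                 glycemia = glycemia, baseline_order = baseline_order,
                 baseline_scale = baseline_scale, scatter_sd = scatter_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

config_grid <- function(config) {
  seq(config$grid_hi, config$grid_lo, by = -config$grid_step)
}

#' Generate one synthetic spectrum
#'
#' The absorbance is the sum of the configured band profiles (amplitudes
#' modulated by group and glycemia), times a multiplicative scatter gain,
#' plus a random smooth polynomial baseline and white noise. Small negative
#' noise excursions are retained — preprocessing must tolerate them — but
#' values driven below `-3 * noise_sd` are clipped to zero; the number of
#' clipped points is attached as attribute `"n_clipped"`.
#'
#' @param record A list or one-row data frame with `sample_id`, `group`,
#'   `glycemia_mgdl`.
#' @param config A [cohort_config()]; the per-sample RNG substream is derived
#'   from `config$seed` and `record$sample_id`.
#' @return An [ftir_spectrum()].
#' @export
generate_spectrum <- function(record, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$bands) == 0) {
    stop("band list is empty", call. = FALSE)
  }
  group <- as.character(record$group)
  if (!group %in% group_levels()) {
    stop("unknown group label: '", group, "'", call. = FALSE)
  }
  wn <- config_grid(config)
  ref <- config$glycemia$mean[["ND"]]
  sig <- numeric(length(wn))
  for (b in config$bands) {
    amp <- b$group_scale[[group]] *
      max(0, b$amplitude + b$glycemia_slope * (record$glycemia_mgdl - ref))
    if (amp > 0) sig <- sig + amp * band_profile(b, wn)
  }
  seed_s <- derive_seed(config$seed, record$sample_id, "spectrum")
  y <- with_seed(seed_s, {
    gain <- 1 + if (config$scatter_sd > 0) {
      stats::rnorm(1, 0, config$scatter_sd)
    } else 0
    baseline <- numeric(length(wn))
    if (config$baseline_scale > 0) {
      tt <- 2 * (wn - min(wn)) / (max(wn) - min(wn)) - 1
      coefs <- stats::rnorm(config$baseline_order + 1L, 0,
                            config$baseline_scale)
      baseline <- drop(outer(tt, 0:config$baseline_order, `^`) %*% coefs)
    }
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(length(wn), 0, config$noise_sd)
    } else 0
    gain * sig + baseline + noise
  })
  clip <- y < -3 * config$noise_sd
  y[clip] <- 0
  s <- ftir_spectrum(wn, y, record$sample_id)
  attr(s, "n_clipped") <- sum(clip)
  s
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-sample glycemia from the configured group distributions and a
#' spectrum per sample. Fully deterministic for a fixed `config$seed`:
#' writing the same configuration twice yields byte-identical files.
#'
#' @param config A [cohort_config()].
#' @return An [ftir_cohort()] with `n_per_group` samples per group; sample
#'   ids are `ND_01`, ..., `D_01`, ..., `D+I_01`, ...
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' print(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  records <- do.call(rbind, lapply(group_levels(), function(g) {
    n <- config$n_per_group[[g]]
    ids <- sprintf("%s_%02d", g, seq_len(n))
    gly <- vapply(ids, function(id) {
      sample_glycemia(g, config$glycemia, n = 1L,
                      seed = derive_seed(config$seed, id, "glycemia"))
    }, numeric(1))
    data.frame(sample_id = ids, group = g, glycemia_mgdl = unname(gly))
  }))
  spectra <- lapply(seq_len(nrow(records)), function(i) {
    generate_spectrum(records[i, ], config)
  })
  ftir_cohort(spectra, records)
}

# linear functional weights of integrate_band() on the config grid:
# trapezoid weights minus the endpoint-chord correction
band_area_weights <- function(config, lo, hi) {
  wn <- sort(config_grid(config))
  idx <- which(wn >= lo & wn <= hi)
  if (length(idx) < 3) stop("integration window too narrow", call. = FALSE)
  x <- wn[idx]
  m <- length(x)
  w <- numeric(m)
  w[1] <- (x[2] - x[1]) / 2
  w[m] <- (x[m] - x[m - 1]) / 2
  if (m > 2) w[2:(m - 1)] <- (x[3:m] - x[1:(m - 2)]) / 2
  L <- x[m] - x[1]
  w[1] <- w[1] - L / 2
  w[m] <- w[m] - L / 2
  list(x = x, w = w)
}

#' Analytic band-area/glycemia correlation of a configured cohort
#'
#' Because band amplitudes are linear in glycemia, the population Pearson
#' correlation between a raw-spectrum band area and glycemia has a closed
#' form, `sign(slope) * S / sqrt(S^2 + N^2)`, with signal SD
#' `S = |slope| * T * sd(G)` (`T` the integration-window transfer of a unit
#' band, `sd(G)` the pooled glycemia SD across the group mixture) and noise
#' SD `N = noise_sd * sqrt(sum(w^2))` from the white noise propagated through
#' the trapezoidal integral. Exact when `scatter_sd = 0`,
#' `baseline_scale = 0`, band amplitudes stay positive and no *other*
#' group-coupled band overlaps the window (overlap adds a small
#' group-mediated covariance); areas must be computed from unnormalized
#' spectra.
#'
#' @param config A [cohort_config()].
#' @param band_label Label of the band in `config$bands`.
#' @param lo,hi Integration window, cm^-1.
#' @return The population correlation (a number in `[-1, 1]`).
#' @seealso [slope_for_correlation()] for the inverse problem.
#' @export
configured_correlation <- function(config, band_label, lo, hi) {
  b <- band_for_label(config, band_label)
  geom <- band_area_weights(config, lo, hi)
  prof <- band_profile(b, geom$x)
  Tt <- sum(geom$w * prof) # window transfer of a unit-amplitude band
  sdG <- pooled_glycemia_sd(config)
  S <- b$group_scale[[1]] * abs(b$glycemia_slope) * Tt * sdG
  N <- config$noise_sd * sqrt(sum(geom$w^2))
  sign(b$glycemia_slope) * S / sqrt(S^2 + N^2)
}

#' Glycemia slope achieving a target area/glycemia correlation
#'
#' Inverts the closed form of [configured_correlation()]: returns the
#' `glycemia_slope` that makes the population correlation between the band's
#' raw area and glycemia equal to `target_r`, given the config's grid, noise
#' level and glycemia mixture.
#'
#' @inheritParams configured_correlation
#' @param target_r Target population correlation in `(-1, 1)`, nonzero.
#' @return The required slope (absorbance per mg/dL).
#' @export
slope_for_correlation <- function(target_r, config, band_label, lo, hi) {
  stopifnot(abs(target_r) < 1, target_r != 0)
  b <- band_for_label(config, band_label)
  geom <- band_area_weights(config, lo, hi)
  prof <- band_profile(b, geom$x)
  Tt <- sum(geom$w * prof)
  sdG <- pooled_glycemia_sd(config)
  N <- config$noise_sd * sqrt(sum(geom$w^2))
  if (N == 0) stop("noise_sd is 0: any nonzero slope gives |r| = 1",
                   call. = FALSE)
  sign(target_r) * N * abs(target_r) / sqrt(1 - target_r^2) /
    (b$group_scale[[1]] * Tt * sdG)
}

band_for_label <- function(config, band_label) {
  labs <- vapply(config$bands, `[[`, character(1), "label")
  i <- match(band_label, labs)
  if (is.na(i)) {
    stop("no band labelled '", band_label, "' in config", call. = FALSE)
  }
  b <- config$bands[[i]]
  if (length(unique(b$group_scale)) != 1) {
    stop("closed-form correlation requires a group-independent band scale",
         call. = FALSE)
  }
  b
}

# SD of glycemia under the group mixture (truncation at 0 ignored)
pooled_glycemia_sd <- function(config) {
  w <- config$n_per_group / sum(config$n_per_group)
  m <- config$glycemia$mean
  s <- config$glycemia$sd
  mbar <- sum(w * m)
  sqrt(sum(w * (s^2 + m^2)) - mbar^2)
}
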