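---
title: "Methods: salivary ATR-FTIR chemometrics in salivaftir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salivary ATR-FTIR chemometrics in salivaftir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivaftir)
```

# The analysis problem

A salivary ATR-FTIR experiment produces, per animal, an absorbance
spectrum on a wavenumber grid (here 3000–400 cm⁻¹ at 4 cm⁻¹ steps, stored
descending per mid-infrared convention) plus covariates: the experimental
group — non-diabetic (ND), streptozotocin-diabetic (D), insulin-treated
diabetic (D+I) — and blood glucose in mg/dL. The scientific questions the
pipeline answers are: (i) which absorption bands change with hyperglycemia
and revert under insulin; (ii) how well a single band area discriminates
diabetic from normoglycemic samples; and (iii) whether whole-spectrum
multivariate models recover the three groups.

# Preprocessing model and assumptions

Raw ATR-FTIR absorbances carry nuisance variation that is not chemistry:
an additive smooth baseline (substrate, scattering) and a multiplicative
per-sample gain (film thickness, contact pressure). The pipeline removes
them in that order:

* **Rubber-band baseline** (default): the lower convex hull of the
  (wavenumber, absorbance) points is interpolated and subtracted. The
  corrected spectrum is non-negative and the operation is idempotent; a
  straight sloped line maps to zero. A simple endpoint-chord
  (`"linear"`) correction is available. The hull assumes bands point
  *upward* from a convex background — valid for absorbance spectra, not
  for derivative spectra.
* **Vector normalization** (default `"opus_vector"`): subtract the mean
  absorbance, then divide by the Euclidean norm of the centered vector,
  giving mean 0 and norm 1. This removes gain exactly: all band areas and
  classification results are invariant to rescaling any single spectrum,
  which is tested as a property.
* **Savitzky–Golay second derivative** (window 9 points, polynomial
  order 3): used only for the multivariate feature space, where it
  suppresses broad baseline remnants and sharpens overlapping bands. The
  derivative is taken with respect to grid *index*; on the constant-step
  grids used throughout this differs from the cm⁻¹ derivative only by a
  constant factor, which is irrelevant after normalization. Boundary
  points use the Savitzky–Golay projection rows (polynomial fits at the
  edges), so the output length equals the input length. The 9/3 defaults
  are the common choice at 4 cm⁻¹ resolution: wide enough to suppress
  noise amplification, narrow enough (~32 cm⁻¹ support) not to merge
  neighboring bands.

Small negative absorbances (noise excursions after correction) are
tolerated by every stage.

# Band quantification and univariate statistics

By the Beer–Lambert law a band's integrated absorbance is proportional to
the concentration of its chromophore. `integrate_band()` computes the
trapezoidal integral over an explicit window after subtracting the local
linear baseline through the window's endpoint absorbances (the behavior of
the usual OPUS-style "method B" integration); the local chord makes areas
robust to residual drift, keeps the operator linear in the spectrum, and
can produce legitimately negative areas, which are reported as-is. Windows
are explicit, reproducible inputs; the defaults (e.g. 1482–1425 cm⁻¹ for
the 1452 band, 860–815 cm⁻¹ for 836) are literature-based half-widths
around the six assignments: 2924 (lipid CH₂), 1549 (amide II), 1452
(protein CH₃ bending), 1313 (amide III), 1120 (phosphorylated saccharide),
836 cm⁻¹ (C₂ sugar conformation). Windows that do not land on grid points
are truncated inward to the covered grid points; at least 3 points are
required.

Group comparisons use one-way ANOVA with Tukey HSD (Tukey–Kramer for the
unbalanced 8/6/7 design) and a Kolmogorov–Smirnov normality check per
group. Normality failures are *reported, not acted on* — the analysis is
parametric throughout, matching standard practice in this literature. A
numerically zero within-group variance with distinct means is flagged
`degenerate` and reported as p = 0 rather than NaN. Band–glycemia
association is Pearson's r with the two-sided t test on n − 2 degrees of
freedom.

# ROC diagnostics

Diagnostic band areas *decrease* in diabetes, so the ROC orientation is
lower-is-positive and the positive class is always D. Two comparisons are
built in: `normo_vs_D` pools ND and D+I as negatives (can the test flag
hyperglycemia regardless of treatment?) and `DI_vs_D` uses only D+I
negatives (can it monitor treatment?). The curve sweeps thresholds at
midpoints between adjacent distinct scores plus ±∞ — ties share a
threshold — and the trapezoidal AUC then equals the tie-corrected
Mann–Whitney statistic, which is asserted against an all-pairs oracle in
the tests. The reported p-value is the two-sided Mann–Whitney test of
AUC ≠ 0.5 (an interpretation; small-sample ROC software differs here).

The cutoff rule is Youden's J = sensitivity + specificity − 1, the field
default for biomarker cutoffs; ties are broken toward higher specificity,
then toward the lower cutoff. Sensitivity, specificity and accuracy are
kept at full precision internally and rounded only for display.

# PCA-LDA with leave-one-out cross-validation

Features are second-derivative, vector-normalized spectra restricted to
3700–500 cm⁻¹ (in practice the intersection with the simulated
3000–400 cm⁻¹ grid). PCA is the eigendecomposition of the covariance
matrix after subtracting the mean spectrum; when spectral points outnumber
samples the dual (Gram-matrix) form is used, which is algebraically the
same decomposition. Variance proportions are taken against total variance,
and component selection supports both a cumulative-variance target
(`select_pcs(target_cumvar = 0.958)`) and a fixed count; the
cross-validation uses a fixed six components when the training fold admits
them (n − 1 ≥ 7), else all available.

LDA uses the pooled within-class covariance with equal priors by default:
group sizes are set by experimental design, not by prevalence, so
proportional priors (available as an option) would be misleading. If the
pooled covariance is ill-conditioned a ridge term λ·trace/d (λ = 10⁻⁶) is
added. Per-class linear discriminant functions and Mahalanobis distances
under the pooled covariance are reported; full quadratic discriminant
analysis is intentionally out of scope.

The cross-validation refits the *entire* pipeline tail — PCA, component
count, LDA — inside every fold, so the held-out spectrum contributes
nothing to the decomposition it is scored against. A `pca_refit = FALSE`
mode fits PCA once on all samples, mirroring workflows that decompose
first and cross-validate only the classifier; it is kept for
comparability, with the caveat that it leaks information and flatters
accuracy. Exact discriminant ties fall back to the first class in label
order, with a warning.

# Ward clustering on spectral regions

Hierarchical clustering operates not on full spectra but on five
concatenated diagnostic regions (A 2995–2889, B 1664–1581, C 1410–1234,
D 1149–1080, E 1018–955 cm⁻¹). Each region slice is vector-normalized
independently, then a single affine map — chosen so the *first* region's
slice spans [0, 1] — is applied to all slices. This is this package's
interpretation of the OPUS "Scaling to 1st Range" option, whose exact
algorithm is not publicly documented: per-region normalization equalizes
region influence, and the shared affine map preserves relative scale
while fixing the display range of region A. The interpretation is
isolated in `scale_to_first_range()` so it can be swapped out.

Ward's minimum-variance linkage is computed on Euclidean distances (via
`stats::hclust` on squared distances), with merge heights reported as the
Ward criterion itself — the increase in total within-cluster sum of
squares per merge — which is non-decreasing by construction. The test
suite verifies the merge sequence and heights against an exhaustive
brute-force agglomeration oracle on 12-sample cohorts. The tree is cut at
k = 3 and clusters are mapped to groups by majority vote (ties to the
larger group, then label order); the traditional alternative of assigning
clusters by dendrogram inspection is not automatable, and majority vote is
the natural mechanical surrogate. Euclidean distance is assumed; whether
the original OPUS analysis used another spectral distance is unknown.

# The synthetic-cohort generator

The generator defines the study conditions under which the pipeline is
exercised and tested:

* **Design**: ND n = 8, D n = 6, D+I n = 7; glycemia drawn per group from
  normal distributions truncated at zero with means/SDs 83.2 ± 4.2,
  497.6 ± 19.6 and 81.0 ± 19.2 mg/dL.
* **Spectrum model**: a sum of Gaussian bands (Lorentzian optional). The
  amplitude of band b in group g at glycemia G is
  `group_scale[g] × max(0, amplitude + slope × (G − 83.2))`. Diagnostic
  bands carry negative slopes — strongest for 1452
  (−1.8·10⁻⁴ AU per mg/dL) and 836 (−1.0·10⁻⁴) — so hyperglycemia
  suppresses them, insulin restores them, and their areas are negatively
  correlated with glycemia, reproducing the qualitative structure of the
  emulated study. Because the coupling is linear, the population
  area–glycemia correlation has a closed form
  (`configured_correlation()`), and `slope_for_correlation()` inverts it;
  the tests use this to configure a population r of −0.80 and verify its
  recovery at n = 1000 within ±0.05.
* **Group separability**: three bands (amide I 1652, and two
  protein/saccharide bands at 1400 and 1240 cm⁻¹) carry group-specific
  scales for D and D+I, emulating the secretory signature of disease and
  treatment. Without them, insulin-treated animals (glycemia restored to
  ND levels) would be statistically identical to ND and the three-group
  classification the study design presumes could not exist. The remaining
  filler bands are identical across groups, so classifiers cannot succeed
  from trivial global intensity. The `effect_scale` argument of
  `default_band_specs()` scales all group couplings jointly; tests verify
  that classification accuracy is monotone non-decreasing across effect
  levels 0.05, 0.4 and 2.
* **Noise model**: additive white noise (SD 0.004 AU — a realistic
  peak-signal-to-noise for co-added ATR scans), a random cubic baseline
  (coefficient SD 0.01 AU), and a multiplicative gain with SD 0.05 on the
  chemical signal. Values driven below −3 × noise SD are clipped to zero
  and counted; smaller negative excursions are retained deliberately so
  preprocessing is exercised on them. No magnitudes were reported for the
  emulated study; these were chosen once for realism and testability.
* **Reproducibility**: one master seed; each sample's RNG substream is
  derived by a stable string hash of its `sample_id`, so enlarging a
  cohort never changes existing samples, and identical configurations
  serialize to byte-identical cohort directories.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: between-animal biological variability in band
amplitudes beyond the glycemia coupling, water-vapor/CO₂ artifacts,
ATR penetration-depth optics, instrument line shapes, and band-position
shifts. Real cohorts overlap more than synthetic ones; with the default
effect sizes the synthetic 1452/836 ROC analyses and both classifiers are
essentially perfect, whereas real data of this design yielded an imperfect
specificity and one misclassified insulin-treated animal. The synthetic
second-derivative spectra also spread variance across many more principal
components (six PCs ≈ 58% cumulative variance at the default noise) than
smooth real spectra do (where six PCs can reach ~96%) — white noise is
heavy-tailed in derivative space.

# Numerical choices and degenerate inputs

* Integration windows narrower than 3 grid points, empty cohorts, empty
  region sets, absent classes and zero-variance correlations are errors
  naming the offending sample, region or metric.
* A constant spectrum cannot be vector-normalized (zero norm → error
  naming the sample); under rubber-band correction it becomes all zeros
  (not an error).
* `select_pcs` compares cumulative variance with a 10⁻⁹ tolerance so a
  target exactly on a floating-point boundary (e.g. 0.958 against
  proportions summing to 0.958) selects the intended count.
* Linear interpolation only in `align_to_grid()` — higher-order schemes
  can invent curvature in sharp bands — and no extrapolation ever.
* The run manifest contains the config hash, seed, version and per-file
  MD5 checksums but no wall-clock timestamps, so that a rerun with the
  same config and seed produces an *identical* manifest; timing goes to
  the console log instead.

# Problem sizes in the test suite

The suite fixes seeds throughout and scales simulations to what the
statistics require rather than to what hardware allows: 10 000 draws for
glycemia moments, 1000 null tables for the ANOVA type-I calibration
(expected rejection 5% ± 2%), 200 permutation replicates × 500 samples
for the null-AUC calibration (mean 0.5 ± 0.03), a 60-sample
permuted-label cohort for the chance-level LOOCV check (≈ 33% ± 10%),
n = 1000 for correlation recovery, and 12-sample cohorts for the
exhaustive Ward oracle. The complete default pipeline (21 samples, 651
grid points) runs in a few seconds on one CPU.

# Known limitations

* The integration windows and the exact OPUS baseline, "Scaling to 1st
  Range" and HCA distance settings of the emulated workflow are not
  public; all are explicit, documented parameters here, but exact
  numerical agreement with OPUS output is not claimed.
* ROC cutoffs are Youden-optimal; other published cutoffs may come from
  different unstated rules, so cutoff values are comparable only within a
  rule.
* Spectral "deconvolution" of the clustering regions (mentioned in some
  workflows without definition) is not implemented; region extraction
  plus normalization stands in its place.
* The LDA is linear; "quadratic distances" reported by some commercial
  tools correspond to Mahalanobis distances under a shared covariance
  here, not to QDA.
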