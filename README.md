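# salivaftir

Chemometric analysis of salivary ATR-FTIR spectra for diabetes monitoring.

Attenuated total reflection Fourier-transform infrared (ATR-FTIR)
spectroscopy turns a 2 µl drop of dried saliva into a vibrational
fingerprint: an absorbance curve over wavenumber (here 3000–400 cm⁻¹ at
4 cm⁻¹ resolution) whose bands report on the sample's proteins, lipids and
saccharides. In a rat model of streptozotocin diabetes, specific salivary
bands — most prominently the asymmetric CH₃ bending mode of protein methyl
groups at 1452 cm⁻¹ and the C₂ sugar conformation band at 836 cm⁻¹ — are
suppressed under hyperglycemia and restored by insulin treatment, making
their areas candidate non-invasive biomarkers for monitoring glycemic
control. This package implements the full analysis chain for that kind of
study, for spectroscopists and biomarker researchers:

- **Preprocessing** — rubber-band (lower convex hull) baseline correction,
  OPUS-style vector normalization (mean-center, scale to unit Euclidean
  norm), Savitzky–Golay second derivatives, mean/difference spectra and
  region extraction.
- **Band quantification** — by the Beer–Lambert law a band's integrated
  area is proportional to analyte concentration; areas are trapezoidal
  integrals over explicit windows after local endpoint-baseline
  subtraction, compared across groups by one-way ANOVA with Tukey HSD and
  correlated with glycemia by Pearson's r.
- **ROC diagnostics** — per-band ROC curves (positive class: diabetic;
  low area = positive), AUC (equal to the Mann–Whitney statistic), and
  Youden-J cutoff selection with sensitivity/specificity/accuracy.
- **Multivariate classification** — PCA (covariance eigendecomposition of
  second-derivative spectra) followed by LDA with leave-one-out
  cross-validation, and Ward hierarchical clustering on five diagnostic
  spectral regions (A 2995–2889, B 1664–1581, C 1410–1234, D 1149–1080,
  E 1018–955 cm⁻¹).
- **Synthetic cohorts** — a seeded generator that emulates the three-group
  study design (non-diabetic ND n = 8, diabetic D n = 6, insulin-treated
  D+I n = 7; glycemia 83.2 ± 4.2, 497.6 ± 19.6, 81.0 ± 19.2 mg/dL) with
  Gaussian bands, glycemia-coupled amplitudes, baseline drift,
  multiplicative scatter and white noise, so the entire pipeline runs and
  is testable with no external data.

Spectra are read and written as CSV (`wavenumber_cm1,absorbance`) or
JCAMP-DX; cohorts are a directory of per-sample files plus a
`metadata.csv` (`sample_id,group,glycemia_mgdl`).

## Worked example

```r
library(salivaftir)

cohort <- generate_cohort(cohort_config(seed = 1))
#> ATR-FTIR cohort: 21 samples (ND=8, D=6, D+I=7), grid 3000-400 cm^-1, 651 points

tab <- band_table(cohort)          # baseline-correct, normalize, integrate
compare_groups(tab, "1452")
#> Band 1452 cm^-1: ANOVA F = 166.4, p = 2.46e-12
#>   ND   n=8  mean=2.2013  sd=0.0495  KS p=0.687
#>   D    n=6  mean=1.7419  sd=0.0554  KS p=0.969
#>   D+I  n=7  mean=2.1623  sd=0.0464  KS p=0.399
#>   Tukey adjusted p-values:
#>     D-ND       p=4.71e-12
#>     D+I-ND     p=0.314
#>     D+I-D      p=3.65e-11

glycemia_correlation(tab, "1452")$r
#> [1] -0.969

ev <- evaluate_band(tab, "1452", "normo_vs_D")
ev$cutoff
#> Cutoff 1.96 (lower-is-positive): sensitivity 100.00%, specificity 100.00%, J = 1.000
#>   counts: TP=6 TN=15 FP=0 FN=0

loocv_pca_lda(cohort)$accuracy   # PCA-LDA, leave-one-out
#> [1] 100
hca(cohort)$accuracy             # Ward clustering on regions A-E
#> [1] 100
```

Reading the output: diabetes suppresses the normalized 1452 cm⁻¹ band area
(Tukey D–ND p ≪ 0.05) while insulin restores it (D+I–ND not significant);
the area is strongly anti-correlated with blood glucose; and a single area
cutoff separates diabetic from normoglycemic animals perfectly in this
synthetic cohort. Both classifiers recover the three groups. Note that the
synthetic generator does not emulate between-animal biological variability
beyond its configured noise terms, so the synthetic cohorts separate more
cleanly than real saliva would (see the methods vignette).

The full pipeline — simulate, validate, preprocess, band statistics, ROC,
PCA-LDA, HCA, manifest — runs in one call and is deterministic per seed:

```r
run_all(pipeline_config(seed = 1), out = "artifacts")
print(report("artifacts"))
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/saliva-ftir.R run-all --seed 1 --out artifacts
Rscript inst/cli/saliva-ftir.R report --in artifacts
```

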