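# mibgquant

Quantification and rater-agreement analysis of cardiac ^123^I-MIBG planar
scintigraphy, for nuclear-medicine methodologists who want to compare
manual versus semi-automatic fixed-size ROI protocols without patient data.

Cardiac ^123^I-MIBG uptake indexes presynaptic sympathetic innervation.
The clinical statistic is the heart-to-mediastinum ratio

    H/M = mean counts/pixel (cardiac ROI) / mean counts/pixel (upper mediastinal ROI)

on early (~15 min) and delayed (~4 h) anterior planar images, classified
pathological when early H/M < 1.9 or late H/M < 1.7 (strict inequality).
The package implements:

* **ROI geometry**: rectangles, ovals, simple polygons, rasterized by a
  pixel-center rule; the *anatomical landmark square* (lung apexes, upper
  cardiac border, medial lung contours) with automatic detection, and the
  fixed-size placement rule (13×20 mediastinal rectangle in the upper half
  of the square; 60×70 cardiac oval at the lower-right quadrant centroid).
* **Agreement statistics from formulas**: ICC(A,1) with F-based 95% CI,
  Fleiss' kappa with subject-resampling bootstrap CI, pairwise Cohen's
  kappa, Spearman rank correlation, Pearson chi-square on 2×2 proportion
  tables, McNemar companion, and the interpretive band systems.
* **A synthetic thoracic phantom**: parametric organs composited onto a
  256×256 expected-count map, organ-specific early→late washout, Poisson
  noise, exact ground-truth H/M, and simulated raters of graded experience
  (Gaussian jitter on landmarks, polygon vertices and the manual
  mediastinal rectangle).
* **A replication pipeline**: cohort → 3 raters × 2 methods → H/M +
  classification → full agreement panel, deterministic under hierarchical
  seeds, with CSV/JSON/text reports and a CLI (`inst/cli/mibg-study.R`).
* **I/O**: tab-delimited count matrices with JSON sidecars, a minimal
  single-frame DICOM dialect (explicit VR little endian, 16-bit), and a
  JSON ROI-set schema.

## Worked example

```r
library(mibgquant)

report <- run_study(study_config(seed = 7, fleiss_B = 500))
print(report)
```

prints (abridged; full panel includes both phases and chi-square tests):

```
== early H/M ratio ==
-- manual method --
  expert     2.35 +/- 0.59   pathological 7/35
  moderate   2.29 +/- 0.57   pathological 6/35
  inexpert   2.25 +/- 0.63   pathological 8/35
  ICC (95% CI): 0.86 (0.77-0.92) [good]
  Fleiss kappa (95% CI): 0.70 (0.34-0.91) [good]
  Cohen kappa expert-inexpert: 0.58 [moderate]
-- semiautomatic method --
  expert     1.73 +/- 0.47   pathological 25/35
  moderate   1.74 +/- 0.46   pathological 24/35
  inexpert   1.74 +/- 0.47   pathological 24/35
  ICC (95% CI): 1.00 (1.00-1.00) [excellent]
  Fleiss kappa (95% CI): 0.91 (0.77-1.00) [very good]
  Cohen kappa expert-inexpert: 0.93 [perfect]
...
== intra-rater agreement (between methods) ==
  expert, early: rho = 0.99 (p = <2e-16)
```

Read: each row is one simulated rater's mean ± SD H/M over the 35-subject
cohort and how many subjects they called pathological. Continuous
agreement (ICC) is excellent for both protocols, but chance-corrected
agreement on the *clinical call* (Fleiss/Cohen kappa) is markedly higher
for the semi-automatic fixed-size protocol — the phenomenon the package
exists to study. (Exact numbers above were produced by this code with
seed 7; your values match when you run the same seed.)

Lower-level entry points: `generate_phantom()`, `generate_cohort()`,
`simulate_rater_rois()`, `detect_landmark_square()`,
`place_semiautomatic_rois()`, `hm_ratio()`, `classify_hm()`, `icc()`,
`fleiss_kappa()`, `cohens_kappa()`, `spearman_rho()`, `chi_square_2x2()`,
`analyze_external()` for your own images/ROIs.

## Limitations

The phantom models count statistics, organ contrast, washout and operator
jitter — not attenuation, scatter or collimator blur; manual and
semi-automatic H/M therefore sit on different absolute scales, and the
package's claims are about within-method reproducibility and
classification agreement, not about reproducing any patient-cohort value.
See `vignettes/mibg-quantification.Rmd` for the full methods discussion.
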