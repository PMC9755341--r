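---
title: "Quantifying cardiac MIBG planar scintigraphy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac MIBG planar scintigraphy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibgquant)
```

## The measurement problem

Cardiac ^123^I-MIBG planar scintigraphy indexes presynaptic sympathetic
innervation of the myocardium. The clinical quantity is the
heart-to-mediastinum (H/M) ratio: mean counts per pixel in a cardiac region
of interest divided by mean counts per pixel in an upper-mediastinal
reference region, computed on an early (~15 min) and a delayed (~4 h)
anterior-view planar image. H/M below 1.9 (early) or 1.7 (late) supports a
Lewy-body disorder. Because the cardiac ROI is traditionally drawn by hand,
the measured ratio — and with it the dichotomous clinical call — depends on
the operator. This package implements two placement protocols and the
statistical machinery to quantify how much they disagree across raters:

* **manual**: a free polygon over the myocardium including the
  left-ventricular cavity, plus a rectangular mediastinal ROI of
  operator-chosen size and position;
* **semi-automatic**: fixed-size ROIs — a 13×20-pixel mediastinal rectangle
  and a 60×70-pixel cardiac oval — placed from an *anatomical landmark
  square* bounded by the lung apexes (top), the upper cardiac border
  (bottom) and the medial lung contours (sides).

Mean (not integrated) counts are used in both numerator and denominator
because the ROI areas differ between methods and raters; this follows the
standardisation literature for fixed-size MIBG ROIs. Classification is
strict: a ratio exactly at the cut-off is non-pathological, matching the
printed "< 1.9 / < 1.7" rule.

## Coordinate and placement conventions

Pixels use 0-based coordinates with `x` = column and `y` = row increasing
downward; the pixel stored at matrix element `[i, j]` has center
`(x, y) = (j - 1, i - 1)`. Rectangles cover half-open index ranges; ovals
and polygons include a pixel iff its center satisfies the inclusion test,
with centers exactly on the boundary included (a deterministic tie-break).
Anterior-view display puts the heart on the image right; a `flip` flag
covers the mirrored convention.

Three published placement phrases needed interpretation, resolved once and
exposed as configuration:

* "13 × 20" is read as width 13 × height 20, and "60 × 70" as a 60-wide ×
  70-tall bounding box (semi-axes 30 and 35) — published protocol
  descriptions leave the orientation unstated, so both are configurable
  (`med_size`, `oval_size`).
* "placed in the half of the anatomical landmark square" is resolved as the
  *upper* half, horizontally centered: the mediastinal rectangle is
  centered at the midpoint of the square's upper half.
* "lower-right quadrant" is taken in displayed-image coordinates: the
  cardiac oval is centered at the centroid of the lower-right quadrant of
  the square and may extend beyond the square, over the myocardium.

Note a geometric consequence of this rule: an oval of half-height 35
centered at 3/4 of the square's height reaches at most `35 - h/4` pixels
below the square (h = square height), so for realistic squares it samples
the *basal* portion of the cardiac silhouette, not the whole ventricle.
The phantom below is designed accordingly.

## The synthetic phantom

No patient images ship with the package; a parametric anterior-view
thoracic phantom stands in for them. Organs are composited in paint order
(background, lungs, mediastinal strip, basal cardiac segment, liver,
myocardial annulus, cavity) onto a 256×256 expected-count map; the late
map applies organ-specific washout factors; Poisson noise is drawn
independently per pixel and per phase. Everything is deterministic given
`(params, seed)`.

Default expected rates (counts/pixel at `acquisition_scale = 1`) are:
soft-tissue background 5, lungs 3 (photopenic relative to soft tissue,
and necessarily below the mediastinum so the medial lung contours are
detectable), mediastinum 6, left-ventricular cavity 8, liver 12,
myocardium 18 (varied per subject), basal segment 0.6 × myocardium.
Washout defaults: 0.80–0.90 per organ, with the myocardial factor drawn
per subject (truncated normal, mean 0.85, SD 0.06) so late ratios sit
slightly below early ones, as in patient series.

Two phantom design choices deserve emphasis:

* **Basal myocardial segment.** The fixed-size oval placed inside the
  landmark square overlaps the main myocardial annulus only over a thin
  band. A phantom containing *only* an annular myocardium would make the
  semi-automatic H/M almost insensitive to cardiac uptake, and the two
  methods' ratio scales would diverge several-fold. Real anterior views do
  not behave that way: the right-ventricular outflow tract and basal
  myocardium lie directly under the lower mediastinum and scale with
  sympathetic innervation. The phantom therefore includes a basal segment
  (ellipse below the upper mediastinum, uptake `basal_fraction = 0.6` of
  the myocardial rate) that the oval samples. It is kept dimmer than the
  detection threshold for the cardiac blob, so it never moves the detected
  upper cardiac border.
* **Landmark square defined on the visible lung fields.** The stored true
  square and `detect_landmark_square()` use the same definition: apexes
  from the painted lung fields, upper cardiac border from the top of the
  myocardial blob, medial contours as the innermost visible lung columns
  over the rows between apexes and cardiac border. On noise-free default
  phantoms detection recovers every edge within 2 px of the stored truth.

**Ground truth.** The true cardiac ROI is the 24-vertex polygon tracing the
outer myocardial ellipse (what a careful manual rater would draw); the true
mediastinal ROI is the 13×20 rectangle placed from the true square. These
masks are disjoint by construction. (The semi-automatically placed oval
cannot serve as the true cardiac mask: under the placement rule it overlaps
the mediastinal rectangle whenever the square is shorter than ~90 px.)
True early/late H/M ratios are computed on the noise-free expected maps
with these masks, via an exact exclusive-region overlap table, and
zero-jitter manual raters reproduce them to machine precision.

**Cohorts.** Per-subject myocardial uptake follows
`LogNormal(meanlog = log 20, sdlog = 0.4)` by default. The two methods
cross their early cut-off at different uptake levels (about 15.4 for the
manual ROIs and 24.3 for the fixed-size oval, computed from the noise-free
default geometry); 20 is the geometric midpoint, so a default 35-subject
cohort straddles both boundaries — roughly a quarter of subjects manual-
pathological and two-thirds to three-quarters semi-automatic-pathological,
the latter matching the order seen in clinical PD series. A consequence
worth stating plainly: the *absolute* H/M scales of the two methods differ
in this phantom (manual ratios run higher), because the phantom models no
collimator blur or scatter, which in real images mix counts into the oval.
Within-method agreement statistics, which is what the package is about,
are unaffected; between-method Spearman correlations remain near 1 because
both ratios are monotone in uptake.

**Simulated raters.** Operator variability is Gaussian and independent per
coordinate: jitter on the four landmark-square coordinates
(semi-automatic), on the 24 polygon vertices and on the mediastinal
rectangle position and log-size (manual). Shipped profiles: expert
(σ~landmark~ 0.5 px, σ~vertex~ 1 px), moderate (1, 2), inexpert (2, 4);
manual rectangle jitter 2/4/8 px position and 0.05/0.10/0.20 log-size.
The rectangle carries the largest jitter deliberately: its size and
position are entirely operator-chosen in the manual protocol ("unspecified
size", free placement along the mediastinum), and removing exactly that
freedom is the mechanism by which the fixed-size landmark-guided protocol
improves agreement. The gap here is real: rater-comparison reports give no
quantitative description of their operators' variability, so these
magnitudes are free parameters of the simulated world, calibrated once so
the simulated manual/semi-automatic agreement ordering matches the
documented phenomenon, and not estimates of any particular clinic's
raters.
Jittered polygon vertices are re-sorted by angle around their centroid so
the drawn contour stays a simple polygon under heavy jitter.

## Agreement statistics

All statistics are implemented from their defining formulas and checked
against independent oracles (brute-force ANOVA via `aov`, hand-evaluated
kappa tables, `mgcv::in.out` for polygon membership):

* **ICC**: two-way random effects, absolute agreement, single rater —
  ICC(A,1) — from the ANOVA mean squares, with F-based 95% limits
  (Satterthwaite degrees of freedom). The source cites agreement
  reliability bands but never names the ICC form; absolute agreement is
  the defensible default for "do raters produce the same number", and a
  consistency form is available by flag.
* **Fleiss' kappa** for three raters on the pathological/non-pathological
  dichotomy, with a subject-resampling bootstrap 95% CI (default
  B = 2000). The asymptotic variance is valid only under the null
  hypothesis of chance agreement, and published panels rarely state their
  CI method, so a bootstrap is used. When every rating falls in one category
  the expected agreement is 1 and kappa is undefined; the implementation
  returns a degenerate flag rather than dividing by zero.
* **Cohen's kappa** per rater pair, from the cross-table.
* **Spearman correlation** between the two methods per rater (intra-rater
  agreement), as Pearson correlation of average ranks with the two-sided
  t approximation.
* **Chi-square** (Pearson, no continuity correction by default; Yates by
  flag) comparing pathological proportions between raters. McNemar's
  paired test is provided as a separate operation but is not used in the
  replication pipeline, which follows the unpaired chi-square design of
  the panels it mirrors.
* **Interpretive bands**: ICC < 0.5/0.75/0.9 poor–moderate–good–excellent;
  Fleiss ≤ 0.2 poor, then fair/moderate/good/very good in 0.2 steps;
  Cohen slight/fair/moderate/substantial/perfect in 0.2 steps.

Two-sided p-values throughout; no multiple-testing correction (none is
part of the mirrored analysis plan).

## Numerical choices and degenerate inputs

* Rasterization: rectangle masks are exact index ranges; oval/polygon
  inclusion uses pixel centers with an inclusive boundary (`<=`, `eps`
  1e-12/1e-9). Polygon filling uses an even-odd scanline with an exact
  per-pixel fallback for degenerate rows (odd crossing counts, horizontal
  edges on pixel-center rows); both paths are property-tested against
  independent oracles.
* `solve_uptake()` inverts the affine relation between myocardial rate and
  both ground-truth ROI means, so point-mass H/M cohort specifications are
  hit exactly even when (at small matrix sizes) the mediastinal rectangle
  clips the basal segment.
* Seeds are hierarchical (`derive_seed(master, ...)`): per-subject,
  per-rater, per-method streams, so adding a subject never perturbs
  earlier subjects' draws.
* The fixed ROI sizes are absolute pixels (the published values are
  matrix-specific); with the default geometry the landmark square is
  smaller than the 13×20 rectangle below a ~128 matrix and placement
  raises an error rather than silently rescaling.
* Degenerate statistics (zero total variance for ICC, one-category
  kappa, constant Spearman input, zero chi-square margin) raise typed
  errors or return explicit degenerate flags; the pipeline propagates
  them with subject/rater/method context.

## What a green test establishes — and what it does not

The phantom emulates count statistics (Poisson), organ contrast, early/late
washout, landmark-square anatomy and graded operator jitter. It does not
emulate attenuation, scatter, collimator blur, anatomical variation between
subjects, or superposition of non-cardiac structures beyond the painted
organs — so passing tests establish that the *pipeline and statistics* are
correct and that the semi-automatic protocol is more reproducible than
manual drawing *under the stated operator-noise model*, not that any
clinical sensitivity/specificity figure is reproduced. Published
patient-cohort values (Table-level means, kappas and their CIs) depend on
undeposited scans and unpublished cross-tables and are deliberately not
asserted anywhere; the acceptance suite instead pins the protocol's exact
geometric constants, the cut-off boundaries, oracle equivalence of every
statistic, parameter recovery on phantoms, and the direction of the
agreement improvement.

## Known limitations

* The two ROI methods sit on different absolute H/M scales in the phantom
  (no blur/scatter); comparisons across methods should stay within rank
  or classification space, as the pipeline does.
* The landmark detector assumes the default phantom's contrast ordering
  (photopenic lungs, hot myocardium); it is exercised on phantoms, not on
  clinical images.
* Fleiss bootstrap CIs are percentile intervals; for n = 35 subjects they
  are approximate (coverage verified ~90–99% in simulation).
* The DICOM dialect is a minimal single-frame explicit-VR little-endian
  writer/reader for interchange of count matrices, not a conformant NM
  IOD implementation.
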