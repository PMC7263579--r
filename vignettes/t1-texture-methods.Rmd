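---
title: "Quantifying diffuse myocardial fibrosis patterns on native T1 maps"
author: "t1tex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diffuse myocardial fibrosis patterns on native T1 maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1tex)
```

## The problem

Native (non-contrast) T1 mapping measures the myocardial longitudinal
relaxation time pixel by pixel. Interstitial fibrosis raises T1, but the
*global* myocardial T1 of hypertrophic (HCM) and dilated (DCM) cardiomyopathy
cohorts overlaps heavily with controls, so a single mean value discriminates
poorly. What differs more reliably between these diseases is the *spatial
pattern* of T1 elevation: HCM tends to show patchy, regional elevation
co-located with wall thickening, DCM a diffuse scattering of small elevated
foci, and healthy myocardium a smooth homogeneous profile. `t1tex`
implements a texture-analysis pipeline that quantifies those patterns:

1. the delineated myocardium of each short-axis slice is unwrapped into a
   standardized rectangle anchored at the inferior right-ventricular (RV)
   insertion point;
2. five slices (base to apex) are stacked into one map per subject;
3. 152 texture features are extracted (10 histogram moments, 44 run-length,
   60 co-occurrence, 38 local-binary-pattern bins);
4. sequential forward selection keeps the few features (default 7) that best
   separate the cohorts under cross-validation;
5. classifiers, a regression-based texture index, ROC/AUC machinery with
   DeLong comparisons, and ICC/Bland–Altman reproducibility statistics
   evaluate the result.

Because clinical T1 maps cannot be redistributed, the package ships a
synthetic phantom generator that reproduces the three cohorts' global-T1
statistics and texture archetypes; every stage of the pipeline is exercised
and tested end-to-end on phantoms.

## The phantom generator

`generate_subject()` renders five annular short-axis slices per subject on a
96 × 96 grid of 2.1 × 2.1 mm pixels. The annulus is mildly elliptical
(eccentricity 0.08), with cavity radius shrinking from 23 mm (base) to 16 mm
(apex) and per-slice centre offsets below one pixel, a stand-in for real
anatomy chosen to look like a mid-ventricular stack rather than to match any
patient. The myocardial T1 field is

> subject mean  +  cohort texture component  +  N(0, 25 ms) pixel noise,

with the subject mean drawn from the cohort's global-T1 distribution:
control 1071 ± 32 ms, HCM 1096 ± 38 ms, DCM 1123 ± 38 ms. The texture
component is:

* **control** – none (homogeneous);
* **HCM** – 2–5 elliptical patches of +90 ms placed at mid-wall inside a
  septal sector whose wall is thickened up to 19 mm (patch angles are drawn
  once per subject and shared across slices, emulating spatially coherent
  regional fibrosis);
* **DCM** – small disk-shaped clusters of +60 ms seeded at about 3.5% of
  myocardial pixels (diffuse scattered elevation).

The texture component is centred over the myocardium before being added, so
the cohort effect size lives entirely in the mean and the texture entirely
in the spatial pattern; this keeps the generator's global-T1 statistics
exactly at the values above, which the tests verify by simulation (3 SE at
n = 200 per cohort).

Pixel noise of 25 ms was chosen so within-wall variability is visually
comparable to clinical maps; patch/cluster amplitudes (90/60 ms) are free
knobs of the phantom, set so patches are conspicuous against that noise
(≈ 3.6 and 2.4 noise SDs). Classification accuracy is a data-bound
quantity, so phantom accuracies are *not* expected to equal clinical ones;
the pipeline-level tests therefore assert directions of effect (texture
beats global T1) rather than magnitudes.

One landmark per slice sits on the epicardial border at the inferior
junction of the annulus, playing the role of the inferior RV insertion
point. All randomness flows from one master seed through a counter-based
substream (subject *i* of a dataset uses seed
`(master %% 19777) * 1e5 + i`), so any subject is reproducible independently
of generation order.

What the phantom does **not** emulate: MRI signal formation and
inversion-recovery fitting, motion and registration artefacts, blood-pool
and extra-cardiac tissue (background is 0), through-plane anatomy, and the
correlation structure of real fibrosis. Passing tests on phantoms therefore
validates the *software* and the *direction* of the method's claims, not its
clinical accuracy.

## Unwrapping the myocardium

`unwrap_slice()` resamples the annulus onto a `rows × cols` rectangle
(default 32 × 192; presets R16 = 16 × 96 and R64 = 64 × 384 keep
`cols = 6 rows`, preserving six 32 × 32 angular segments per slice at every
preset). For column *c* the sampling ray leaves the cavity centre (the
endocardial contour centroid) at angle

> θ(c) = θ_landmark + 2π (c + 0.5) / cols,

proceeding clockwise in displayed-image orientation (y axis down — this
flips if contours are stored in physical coordinates, which is why the
convention is fixed here). Border radii per angle come from piecewise-linear
ray/contour intersection; row *r* samples at fractional depth
(r + 0.5)/rows between the endo- and epicardial radii, so samples are
strictly interior and the map has no gaps. Row 1 is the endocardium —
the choice is arbitrary but fixed, because run-length and LBP directions
are defined on the rectangle. Slices stack base→apex, top→bottom.

Interpolation is bilinear with one refinement: background pixels (exactly 0
or non-finite) are excluded from the 2 × 2 support and the remaining weights
renormalized. Plain bilinear would mix background zeros into every
near-border sample (the outermost sample depths sit within half a pixel of
the borders) and drag border T1 toward 0; masked renormalization keeps a
constant annulus exactly constant and preserves the myocardial mean within
1% on smooth phantoms (both tested). If an entire 2 × 2 support is
background — possible only when contours were drawn loosely, as in the
re-contouring experiments — the nearest myocardial pixel within 4 pixels is
used; beyond that the slice is rejected with an error naming the angle.

## The 152 texture features

All features operate on the stacked 160 × 192 map as one image (supported by
the idea of simultaneous feature extraction from multiple slices; the
alternative — per-slice extraction then averaging — would wash out
slice-to-slice differences).

* **Histogram (10)** — mean, population variance, skewness, kurtosis, and
  standardized central moments of orders 5–10. A zero-variance map defines
  all standardized moments as 0, so the extractor is total on degenerate
  inputs.
* **Quantization** — co-occurrence and run-length features first quantize
  the stacked map into 32 equal-width levels between its min and max (the
  number of levels is configurable). Min–max-relative quantization makes
  these families invariant to intensity shifts, which is desirable: global
  T1 offsets are already captured by the histogram mean. A constant map
  quantizes to level 0 everywhere by convention.
* **GLRLM (44)** — 11 run-length statistics (SRE, LRE, GLN, RLN, RP, LGRE,
  HGRE, SRLGE, SRHGE, LRLGE, LRHGE) in each of 4 directions (0°, 45°, 90°,
  135°). Gray-level weights use (i + 1) with levels indexed from 0 so
  low-gray-level emphasis features never divide by zero.
* **GLCM (60)** — 6 Haralick-type statistics (angular second moment,
  contrast, homogeneity, entropy, correlation, sum of squares) at
  displacements 1–10 pixels. The 6 × 10 = 60 layout forces aggregation over
  direction: counts are *pooled* (summed) across the 4 directions per
  displacement before normalization, rather than averaging per-direction
  feature values — pooling keeps the joint distribution interpretation and
  is the documented choice. "Homogeneity" is implemented as the inverse
  difference moment Σ p/(1 + (i − j)²); among the inverse-difference
  variants this is the most common reading, but it is a convention, not a
  certainty. Correlation on a single-level map is defined as 0.
* **LBP (38)** — rotation-invariant uniform (riu2) codes with P = 36
  circular neighbors (38 bins = P + 2 forces P = 36) at radius R = 2 pixels
  (radius is a free knob; 2 px keeps the operator inside the 32-row slice
  band). Neighbors are sampled bilinearly; a neighbor equal to the centre
  counts as 1, with a relative tolerance of 1e-9·max|map| so exact ties are
  not broken by floating-point round-off. The histogram is normalized over
  pixels whose full neighborhood lies inside the map; bins are named
  `LBP(1)`…`LBP(38)` with bin b holding code b − 1.

Feature names are canonical strings — `GLN(135)`, `SRHGE(0)`, `LBP(8)`,
`Contrast(3)` — so selected features are addressable in reports and CSV
headers. Circularly shifting the stacked map's columns (a landmark shift)
moves LBP bins by less than 0.05 on homogeneous phantoms; the residual
motion comes from the changed interior support at the left/right edges.

## Selection, classification, and the texture index

`sfs()` performs sequential forward selection: at each step the candidate
whose inclusion maximizes stratified 10-fold CV accuracy of a linear
maximum-margin classifier (soft-margin SVM, cost 1) joins the set; ties
break to the lowest feature index; the default stops at k = 7 features. The
fold assignment is seeded and reused across all candidate evaluations of all
steps, making selection deterministic and bit-reproducible. Normalization
is fit on training folds only by default; `global_norm = TRUE` reproduces the
simpler global mean/variance normalization (slightly optimistic, as the
test folds then leak into the scaling — kept as an option for comparability,
not as the default).

`cross_validated_eval()` evaluates linear SVM, RBF SVM, KNN, or bagged
ensemble trees under the same stratified CV. Hyperparameters are deliberately
plain defaults — SVM cost 1, KNN k = 5, 200 trees — exposed but not tuned.
KNN is implemented in-package with a deterministic lowest-class-index
tie-break (randomized tie-breaking would violate seed-reproducibility), and
SVM class labels come from one-vs-one voting while ROC scores come from
per-class one-vs-all margins. One-vs-all ROC curves use descending score
thresholds and trapezoidal AUC; AUC confidence intervals and comparisons use
DeLong's structural components with midranks for ties.

`texture_index()` is the binary-comparison summary: OLS of the ±1 cohort
coding on the selected features, `Tx = b0 + b1 x1 + … + bn xn`, with the
first-listed cohort coded +1 — so positive Tx points to the first cohort.
With a rank-deficient design the minimum-norm solution is used.

Baselines mirror the clinical comparison: a global-T1-only classifier
(1 feature) and a segmental-T1 classifier (30 features: 6 angular segments ×
5 slices, segment 1 starting at the landmark).

`icc_two_way_mixed()` implements ICC(3,1), the single-measure consistency
form of the two-way mixed model, with the absolute-agreement variant behind
`type = "agreement"` ("two-way mixed" alone does not pin down the form;
consistency ICC(3,1) is the default here and the choice is exposed).
Observer variability is emulated on phantoms by `perturb_contours()`:
smooth seeded radial jitter (SD 1 pixel by default) followed by a full
re-run of unwrap + extraction.

`embed_2d()` is an exact (O(n²)) t-SNE for cohort-sized tables, written in
base R: perplexity-calibrated Gaussian affinities, early exaggeration,
momentum gradient descent, deterministic given a seed. It is visualization
plumbing, not part of the statistical claims.

## Numerical conventions and degenerate inputs

* Constant maps: variance/skewness/kurtosis/higher moments 0; single GLCM
  cell (ASM 1, contrast 0, entropy 0, correlation 0); all-ones LBP word
  (bin 37 mass 1).
* Stacked-map quantization maxima land in the top bin (half-open bins,
  closed at the top).
* 0·log 0 = 0 in entropy; GLCM probabilities always sum to 1.
* DeLong on identical score vectors returns ΔAUC = 0, p = 1 (zero-variance
  guard); degenerate rating tables (no between-subject variance) return
  ICC = 0 with a warning.
* Wall thickness below 2 pixels anywhere makes a slice unwrappable and is
  an error at generation and unwrap time.

## Problem sizes used in tests and the acceptance script

The shipped experiments run at desk scale, chosen as the smallest sizes at
which the stochastic assertions have comfortable margins: 50 subjects per
cohort for the main study (the clinical study had 65/116/140), 20 per cohort
for the resolution sweep, 200 per cohort for generator-calibration checks,
and 20 master seeds for the selection-recovery simulation. The
selection-recovery design plants two informative features (2-SD class-mean
separation) among 150 noise features, n = 150, and requires both to be
found within the first 3 picks in ≥ 90% of seeds.

## Known limitations

* Phantom texture parameters are free knobs: classifier accuracy on
  phantoms does not estimate clinical accuracy, only the ordering of
  methods (texture > global T1) and the machinery's correctness.
* The unwrap assumes a star-shaped myocardium about the endocardial
  centroid — true for short-axis LV slices, not for arbitrary shapes.
* Features are 2-D on the stacked map; runs and co-occurrences can cross
  slice boundaries at the 5 stack seams (1.6% of row pairs at default
  resolution). Treating the stack as one image was the documented choice.
* Reported GLRLM selections in the source literature are ambiguous about
  direction labels; all 4 directions are first-class features here and no
  attempt is made to resolve that ambiguity.
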