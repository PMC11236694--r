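---
title: "Methods: quantifying hemocyte localization in abdomen sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying hemocyte localization in abdomen sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemospat)
```

## Overview

`hemospat` asks a deceptively simple question of sectioned fly abdomens: are
the hemocytes *where* they usually are? Because absolute counts often do not
change while localization does, the package couples cell segmentation with
spatial point-pattern statistics and a per-fly nonparametric comparison.
This vignette documents the models, the tunable parameters, the numerical
conventions, and the choices made where the design was genuinely open.

## The synthetic-data generator

No public image set accompanies this kind of analysis, so the package ships
a generator whose output every downstream stage is tested against.

**Windows.** A section outline is modeled as an ellipse (default semi-axes
150 x 90 µm) radially perturbed by a random Fourier series over harmonics
2-5 whose coefficients sum to the `boundary_jitter` amplitude (default
0.12). Because the perturbation is radial and below 0.5, the polygon is
star-shaped, hence simple; 180 vertices keep the discretized area within
0.1% of the ideal ellipse. Real section outlines are irregular closed
curves of varying size; the jittered ellipse reproduces that at the level
the statistics care about (area, centroid, boundary distance) without
modeling tears or lobes.

**Point processes.** The generator offers three regimes:

* `csr` — a homogeneous Poisson process: count `Poisson(intensity * area)`,
  uniform locations ("fed-like" dispersal).
* `center_biased` — the same Poisson count, but each location is accepted
  with probability `(1 - d/dmax)^bias_exponent` where `d` is the distance
  to the window centroid. With the default exponent 2 this reproduces the
  "starved-like" agglomeration toward the centroid while keeping expected
  counts exactly matched to `csr` — the property the comparison tests
  exploit.
* `thomas_cluster` — Poisson parents with Gaussian-dispersed,
  Poisson-sized offspring, for contact-level clustering.

These regimes are stand-ins chosen to reproduce the qualitative contrasts
of interest (unchanged abundance, shifted localization); they are not
claims about hemocyte biology. The default intensity of 0.0025 points/µm²
yields roughly 100 cells per ~42,000 µm² section, a realistic density for
tagged hemocyte populations in abdominal sections.

**Rendering.** Each point becomes an isotropic Gaussian blob
(`psf_sigma` = 2 µm, peak 180 counts on an 8-bit scale) over additive
Gaussian background noise (mean 12, sd 4), at the calibration of 0.207
µm/px used throughout. Tissue signal is confined to the window; pixels
outside carry background only. The model deliberately omits Poisson shot
noise, optical aberrations, multi-channel structure, and 3D — it is
sufficient for exercising thresholding and watershed behavior, which is
its job. Consequently, passing tests demonstrate correctness of the
algorithms, not robustness to every artifact of real microscopy (uneven
illumination, debris, section tears).

**Reproducibility.** A cohort derives one integer substream seed per
section from `(root seed, condition, fly, section)` by counter-based
arithmetic modulo 2^31 - 1, so any section can be regenerated alone and
cohorts are byte-identical across runs and platforms.

## Segmentation

The detection chain mirrors a standard QuPath-style workflow:

1. **Yen threshold.** The histogram-entropy criterion
   `TC(t) = -log(G1 G2) + 2 log(P(1-P))` is maximized over the native
   histogram — 256 integer levels for 8-bit images, 1024 equal-width bins
   for 16-bit. The returned threshold is the upper edge of the maximizing
   bin, so it always lies strictly between the image extremes; ties across
   the plateau of equivalent splits resolve to the lowest bin. A constant
   image has no separating threshold and errors.
2. **Background suppression.** Pixels strictly below the threshold are
   zeroed (idempotent by construction).
3. **Watershed detection.** After Gaussian smoothing (default sigma 1 px)
   the suppressed intensity surface is flooded from local maxima; maxima
   closer in height than `watershed_tolerance` (default 1 count) merge, so
   touching blobs separate along their valley. Regions are filtered by
   area (default 20-200 µm², bracketing the ~78 µm² footprint of a ~10 µm
   hemocyte), by mean intensity (defaulting to the Yen threshold), and by
   requiring the centroid inside the window — a region touching the
   boundary is kept if its centroid is interior, matching centroid-based
   feature exports.

Coordinates use the top-left pixel center as origin, x along columns and y
along rows, exported in µm as `index * pixel_size`. The exact watershed
variant and score-compartment settings of interactive tools are not
recoverable from any published description; the smoothed-intensity
watershed with exposed parameters is this package's own, tested,
equivalent.

## Spatial statistics

**Percentile annuli.** The construction "split the circumcircle into ten
parts" admits only one algebraically consistent reading: with
`R_i = Rc * sqrt(i/10)` the ten annuli have equal area `pi Rc^2 / 10` and
`R_10 = Rc`. (The transposed form `R_i = Rc * sqrt(10/i)` would place every
radius outside the circumcircle.) The package implements the equal-area
reading and asserts the invariant to 1e-9 relative tolerance.

**Centroid ECDF.** The proportion of cells within each `R_i` is
nondecreasing and ends at 1 by construction. Replicate curves are averaged
across sections (the replicate unit of the motivating figures);
aggregation across flies is available by first averaging a fly's sections.
The 95% band is the normal approximation `mean ± 1.96 s/sqrt(m)` truncated
to [0, 1]; with a single curve the band is flagged undefined rather than
fabricated.

**G-function.** "Distances of the 5 nearest neighbors" is read as pooling
each cell's 1st..5th neighbor distances into one per-section multiset
before taking the ECDF; per-j curves are available by calling with k = 1..5
separately. Sections with n <= k cells are excluded with a warning and
recorded as missing, never imputed. No edge correction is applied (none is
standard in this workflow); validation against the closed CSR form
`1 - exp(-lambda pi r^2)` therefore restricts query points at least the
maximum grid distance away from the boundary, where the uncorrected and
corrected estimators coincide.

**Delaunay summaries.** Neighbors are points sharing a triangulation edge
(computed with `deldir`), optionally pruned at `max_edge` (default: no
pruning, the least surprising behavior; a pruned edge also removes its
triangles). Without pruning the triangle statistics use two exact
identities — any triangulation of all n points has `2n - 2 - h` triangles
(h = hull vertices) tiling the convex hull — so the mean-triangle-area
fraction needs no triangle enumeration; the explicit triangle list is
extracted on demand and is verified in the tests against the defining
empty-circumcircle property. Patterns with n < 3 or collinear points have
no triangulation and return an `undefined` summary.

**Normalization.** For pooled 2D histograms, sections are registered by
translating the window centroid to the origin and scaling by 1/Rc, mapping
each pattern into the closed unit disk. If every cell sits exactly at the
centroid, Rc = 0 and all normalized coordinates are returned as the origin
with a note.

## Comparison

**Quality control.** "Comparable area" is operationalized as a median-ratio
window: sections within [0.5, 1.5] x the cohort median area are kept, and
every exclusion is logged with the violated bound, making the filter
auditable. The thresholds are configuration-exposed because the underlying
rule is a judgment call.

**Experimental unit.** Section values are averaged per fly before testing;
flies, not sections, are exchangeable units under the design.

**Mann-Whitney U.** The statistic is computed from midranks
(`U = #(x_i > y_j) + 0.5 #ties`). With both samples at most 8 and no ties
the two-sided p-value uses the exact null distribution of U (identical to
the permutation distribution over all labelings, which the tests verify
exhaustively for all sizes up to 6 vs 6); otherwise the normal
approximation with tie-corrected variance and continuity correction is
used, and the method applied is recorded in the result. The cutoff at 8
keeps the exact path for fly-sized samples while avoiding large exact
tables; a forced-exact switch is available. Unadjusted p-values are
reported — one pre-specified test per statistic — with a Holm column added
for transparency.

## Problem sizes used in the test suite

The suite exercises the statistics at the scales at which their guarantees
are informative while staying lightweight: the CSR-vs-closed-form check
uses lambda = 0.005 points/µm² in a 1000 x 1000 µm window (~5,000 points)
with a 50 µm interior guard; oracle-equivalence checks run 50 random
fixtures of up to 50 points; the type-I simulation uses 200 cohorts of
8 + 10 flies x 3 sections and the power simulation 100 such cohorts on
ground-truth patterns (segmentation contributes nothing to those
hypotheses); segmentation recovery uses 20 rendered sections of 50
well-separated blobs at SNR 45. The acceptance script scales the
simulations to 50 runs per regime.

## Known limitations

* The generator's noise model is Gaussian-additive only; detection
  performance on real images with structured background will be worse than
  the synthetic F1 suggests.
* The G-function carries no edge correction, so absolute curve values near
  the boundary are biased low; between-condition comparisons on matched
  window geometry are unaffected.
* The center-biased process models radial attraction only; anisotropic
  niches (e.g. organ-adjacent accumulation) would need a different kernel.
* Mann-Whitney on 8-10 flies has limited power for subtle shifts; the
  pipeline reports effect directions via per-fly values for inspection.
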