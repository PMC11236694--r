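# hemospat

Spatial statistics for hemocyte localization in cryosectioned fly abdomens.

## The problem

Drosophila hemocytes — the fly's macrophage-like blood cells — redistribute
within the abdominal cavity in response to physiological challenges such as
starvation. In sectioned abdomens the interesting question is usually not
*how many* hemocytes there are but *where* they sit: total counts can stay
flat while the cells agglomerate toward the section centroid. Detecting that
shift requires segmenting fluorescently tagged cells from section images and
then comparing spatial point-pattern statistics between experimental groups,
with the fly (not the section) as the experimental unit.

`hemospat` packages that whole analysis for R users, together with a
synthetic-data generator so that every stage — segmentation, statistics,
group comparison — can be validated against known ground truth without any
microscopy data.

## What it computes

For a point pattern \(X = \{x_1,\dots,x_n\}\) inside a section window with
centroid \(c\):

* **Percentile-distance ECDF.** With \(R_c = \max_i \lVert x_i - c\rVert\)
  (the circumcircle radius) and radii \(R_i = R_c\sqrt{i/10}\), the ten
  concentric annuli have equal area \(\pi R_c^2/10\), and the curve
  \(F(i) = \#\{\,\lVert x-c\rVert \le R_i\,\}/n\) gives the proportion of
  cells within each percentile distance. Replicate curves are averaged with
  a 95% band \(\bar F \pm 1.96\,s/\sqrt{m}\).
* **k-nearest-neighbor G-function.** The empirical CDF of the pooled
  distances from each cell to its 1st..k-th nearest neighbors (k = 5 by
  default). Under complete spatial randomness the k = 1 curve is
  \(G(r) = 1 - e^{-\lambda \pi r^2}\), which the tests use as a closed-form
  oracle.
* **Pairwise-distance histograms** over all \(n(n-1)/2\) unordered pairs.
* **Delaunay neighborhood summaries**: neighbor-degree histogram, triangle
  count, and mean triangle area as a fraction of the window area.
* **Group comparison.** Section-area quality control, per-fly averaging,
  and two-sided Mann-Whitney U tests
  (\(U = \#\{x_i > y_j\} + \tfrac12\#\{\text{ties}\}\), exact null
  distribution for small tie-free samples) on hemocyte count, % area
  occupied, median 1st-NN distance, median distance-to-centroid, and the
  Delaunay area fraction.

Images are processed with Yen entropy thresholding, background suppression,
and watershed splitting of touching cells; the synthetic generator renders
Gaussian-blob fluorescence over jittered-ellipse windows under CSR,
center-biased, or Thomas-cluster point processes at 0.207 µm/px.

## Worked example

```r
library(hemospat)

co <- generate_cohort(n_flies = c(4L, 5L), sections_per_fly = 3L,
                      fed_spec = scene_spec(process_kind = "csr"),
                      starved_spec = scene_spec(process_kind = "center_biased"),
                      seed = 1, render = FALSE)
stats_df <- do.call(rbind, lapply(co$patterns, section_statistics))
report <- run_comparison(stats_df, patterns = co$patterns)
report
#> <hemocyte_comparison> fed vs starved, 27 sections kept, 0 dropped
#>                    statistic  U    p_value method n_fed n_starved     p_holm
#>               hemocyte_count 12 0.73015873  exact     4         5 0.73015873
#>           median_nn_distance 20 0.01587302  exact     4         5 0.06349206
#>     median_centroid_distance 20 0.01587302  exact     4         5 0.06349206
#>  mean_triangle_area_fraction 20 0.01587302  exact     4         5 0.06349206
```

The two simulated conditions have matched expected counts, and the count
comparison is correspondingly null (p = 0.73). The localization statistics
separate completely (U = 20 is the maximum for 4 vs 5 flies; p = 0.016 is
the smallest two-sided exact p at these sample sizes): starved-like
patterns sit closer to the centroid, closer to each other, and form smaller
Delaunay triangles. `plot_comparison(report, "median_centroid_distance")`
draws the per-fly panel, and `plot_curve_set()` renders the ECDF /
G-function bands.

The full image-based pipeline (simulate → TIFF rendering → segmentation →
statistics → comparison) runs with `run_pipeline(pipeline_config(...))` or
from the shell via the `inst/cli/hemospat` script:

```sh
Rscript inst/cli/hemospat all --seed 1 --outdir run1
```

Every run writes tidy CSV outputs plus a JSON summary with the config hash,
and is byte-identical for a fixed seed and configuration.

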