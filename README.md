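# fascicle3d

Quantifies the three-dimensional fiber-bundle (fascicle) architecture of
skeletal muscle from serially digitized point data, built around the torn
supraspinatus. It is aimed at morphometry and biomechanics groups who
digitize fascicles *in situ* with a tracked stylus during serial dissection
and need reproducible fiber bundle lengths, pennation angles and
tear-severity statistics — plus a fully synthetic digitized-specimen
generator so the entire pipeline is testable without cadaveric data.

## The method

Each digitized fascicle (ordered 3D sites, medial → lateral, in cm) is
reconstructed as an interpolating cubic **Catmull–Rom spline** (centripetal
knots, reflected phantom endpoints) and reparameterized by arc length.

* **Fiber bundle length**: FBL = total arc length of the spline, computed by
  dense per-segment quadrature — bounded below by the endpoint chord and
  invariant under rigid motion.
* **Line of force**: the first principal axis (total least squares line) of
  the digitized intramuscular tendon-axis points, oriented medial→lateral;
  one axis per muscle region.
* **Pennation angles**: with t̂ the normalized average of unit tangents over
  the terminal 10% of arc length at an attachment and d̂ the line-of-force
  direction, PA = arccos |t̂ · d̂| ∈ [0°, 90°]; computed at the lateral and
  medial attachments separately.
* **Tear severity**: A = partial-thickness tear, B = full-thickness without
  retraction, C = full-thickness with retraction (tear spans the tendon's
  full sagittal width). Largest tear diameters are maximum pairwise extents
  of the tear boundary projected onto landmark-derived coronal/sagittal
  planes.
* **Statistics**: median (min–max) per region × part × category cell;
  tie-corrected Mann–Whitney U (asymptotic without continuity correction,
  the convention that reproduces SPSS p-values, plus an exact-enumeration
  variant), Kruskal–Wallis with tie correction, and Bonferroni-adjusted
  pairwise comparisons (α/m, e.g. 0.05/3 = 0.0167).

All user-facing functions take data frames first and return tibbles; test
objects have `tidy()`/`glance()` methods and summaries have `autoplot()`.

## Worked example

```r
library(fascicle3d)
library(dplyr)

# packaged reference cohort: 12 cadaveric shoulders
tab <- reference_specimens()
describe(tab$age)
#>       n  mean    sd   min   max median
#> 1    12  82.1  10.8    64    95   82.5

# tear dimensions, category B vs C (tie-corrected, no continuity correction)
B <- filter(tab, category == "B"); C <- filter(tab, category == "C")
mann_whitney(B$coronal_cm, C$coronal_cm)
#> <Mann-Whitney U> (asymptotic_tie_corrected)
#>   statistic = 0.0000, z = -2.3233, p = 0.02016
#>   n = 4, 4
```

The mean specimen age is 82.1 ± 10.8 years (range 64–95), and the
category-C coronal tear diameters are significantly larger than category B
(U = 0, complete separation; two-sided p = 0.020). The exact-permutation
variant cannot produce p below 2/70 ≈ 0.029 at 4 vs 4, which is why the
asymptotic method is the default.

```r
# synthetic cohort -> measurement -> summary (small sizes for the example)
cfg <- generator_config(seed = 1, bundles_per_layer = c(8, 12), layers_per_part = 1)
cohort <- generate_cohort(cfg, n_per_category = 4)
cohort
#> <fascicle_cohort> 12 specimens (A:4 B:4 C:4), 649 fiber bundles, seed 1

meas <- measure_bundles(cohort$points) |>
  left_join(cohort$specimens[, c("specimen_id", "category")], by = "specimen_id")
summ <- summarize_architecture(meas, by_part = FALSE)
architecture_table(summ, "fbl_cm")
#>   region    category n_specimens whole
#> 1 anterior  A                  4 6.82 (3.19-14.69)
#> 2 anterior  B                  4 5.11 (2.50-10.18)
#> 3 anterior  C                  4 2.85 (1.43-5.68)
#> 4 posterior A                  4 6.06 (3.14-11.17)
#> 5 posterior B                  4 4.89 (2.10-8.47)
#> 6 posterior C                  2 3.03 (1.67-6.91)
```

Median FBL decreases monotonically with tear severity in both regions
(anterior 6.82 → 5.11 → 2.85 cm), and the category-C posterior cell is
backed by only two specimens — such cells are summarized but excluded from
hypothesis testing. `autoplot(summ)` draws the median/range cells;
`compare_architecture(meas)` runs the Kruskal–Wallis + pairwise workflow;
`write_obj_model()` exports a specimen as Wavefront OBJ polylines.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/fascicle3d.R generate --out cohort/ --seed 42
Rscript inst/cli/fascicle3d.R measure  --in cohort/ --out measured/
Rscript inst/cli/fascicle3d.R report   --in measured/ --out report/
```

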