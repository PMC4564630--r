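---
title: "Quantifying 3D fiber-bundle architecture of the torn supraspinatus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D fiber-bundle architecture of the torn supraspinatus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fascicle3d)
library(dplyr)
```

## The measurement problem

Rotator-cuff tendon tears remodel the supraspinatus muscle: fascicles (fiber
bundles) shorten as the musculotendinous unit retracts, and their pennation
angle — the angle between fascicle orientation and the muscle's line of force
— increases. Because fiber bundle length (FBL) sets a muscle's excursion and
contraction velocity, and pennation sets how much fiber force projects onto
the tendon, these two parameters largely determine residual function of the
pathologic muscle.

`fascicle3d` implements the quantification pipeline for serially dissected,
stylus-digitized specimens. The input is a long table of ordered 3D points
(cm): for each fascicle 10–20 digitized sites from the medial to the lateral
attachment, plus tendon outline dots, points along the intramuscular tendon
axis, three bony landmark points (lateral scapular spine, coracoid process,
greater tubercle), and tear metadata. The muscle is treated as two regions
(anterior, penniform; posterior, fusiform) each with superficial, middle and
deep parts; those labels come from dissection and are inputs, never inferred
from geometry.

## The measurement model

For each digitized fascicle:

1. **Spline reconstruction.** The ordered sites are interpolated by a cubic
   Catmull–Rom spline. Knots follow the *centripetal* convention
   (squared-chord exponent 0.5) by default; uniform and chordal variants are
   available. Centripetal knots avoid cusps and loops on unevenly spaced
   sites, and because everything downstream is reparameterized by arc
   length, results are insensitive to this choice. The two phantom neighbors
   a Catmull–Rom segment needs beyond each end are obtained by reflection
   (`2*P1 - P2`), which preserves the direction of the terminal chord.
2. **Arc-length parameterization.** Each spline segment is sampled densely
   (200 subdivisions per segment by default) and cumulative chord lengths
   give a monotone arc-length table, inverted to resample the curve at
   `n_samples = 100` positions equally spaced in arc length.
3. **Fiber bundle length** is the total arc length of the spline. It is
   bounded below by the endpoint chord, invariant under rigid motion, and
   scales linearly under uniform scaling.
4. **Line of force.** The axis of the intramuscular tendon is estimated as
   the first principal axis (total least squares line) of the digitized
   tendon-axis points, oriented medial-to-lateral, anchored at their
   centroid. One axis is fitted per region by default (`lof_per_region`),
   since the anterior and posterior regions insert on separate tendons; a
   single global axis is available as a configuration.
5. **Pennation angles.** The fascicle orientation at each attachment is the
   normalized average of unit tangents at 20 positions spread over the
   terminal 10% of arc length (`region_fraction = 0.10`); averaging
   stabilizes the estimate against digitization noise at the attachment.
   The pennation angle is `acos(|t . d|)` in degrees, folded to [0, 90] —
   the acute angle, matching the reporting convention of the field. Lateral
   and medial angles are computed from the lateral and medial end tangents
   respectively.

Tunable parameters, all in `geometry_config()`:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 100 | uniform arc-length samples stored per fascicle |
| `region_fraction` | 0.10 | terminal arc fraction for tangent averaging |
| `knot_parameterization` | centripetal | Catmull–Rom knot rule |
| `quadrature_subdivisions` | 200 | per-segment arc-length sampling |
| `tangent_samples` | 20 | tangent positions averaged per end |
| `lof_per_region` | TRUE | one line of force per region |

The 10% tangent region is a convention: the source protocols average
"derivatives over the lateral and medial regions" without quantifying the
extent. It is exposed so users can study sensitivity; values above ~0.2 blur
genuinely curved fibers, values below ~0.05 become noise-dominated on
sparsely digitized fascicles.

## Tear severity and tear dimensions

Tears are classified A (partial thickness), B (full thickness without
retraction) and C (full thickness with retraction), where retraction means
the tear spans the tendon's entire sagittal width. A partial tear flagged as
spanning the full width is rejected as contradictory.

Caliper-style tear dimensions are computed from a digitized tear boundary:
the boundary is projected orthogonally onto the coronal and sagittal planes
and the diameter in each plane is the *maximum pairwise distance* of the
projected points (the largest caliper opening), not the extent along a
single axis. The anatomical planes are derived from the landmark frame: the
medial-lateral axis points from the scapular spine landmark to the greater
tubercle; the anterior-posterior axis is the orthogonalized direction toward
the coracoid; the superior-inferior axis completes a right-handed triad.
Coronal = medial-lateral x superior-inferior; sagittal = anterior-posterior
x superior-inferior. This is a convention — the original caliper protocol
did not record how its planes related to the landmark screws — but it is
deterministic, equivariant under rigid motion, and testable. A boundary that
collapses to a point after projection yields a zero diameter with a warning
rather than an error.

Left shoulders are mirrored across the sagittal plane onto a canonical
right-side frame when a cohort is loaded (`mirror_left = TRUE`), so pooled
statistics are side-agnostic; both FBL and the folded pennation angles are
invariant under that reflection.

## Statistical layer

Architecture is summarized as median (min–max) per cell — a cell being a
region x part x tear-category combination, or region x category with parts
pooled. Fiber bundles are pooled across the specimens of a category, the
same unit of analysis as the reference workflow; the min–max spans in the
published tables clearly reflect bundle-level variation, and no
specimen-level clustering correction is applied (a known limitation, noted
below).

Inference uses nonparametric rank tests implemented in the package:

* `mann_whitney()` — U from midrank sums. The default method is the
  asymptotic normal approximation with tie-corrected variance and **no
  continuity correction**: `z = (U - n1 n2/2)/sigma`,
  `sigma^2 = n1 n2/12 ((N+1) - sum(t^3 - t)/(N(N-1)))`. This is the SPSS
  convention; at 4 vs 4 specimens the exact test's smallest attainable
  two-sided p is 2/70 = 0.0286, so published tear-dimension p-values of
  0.020/0.021 can only arise from the asymptotic formula — reproducing them
  pins down the method. The `"exact"` method enumerates all
  `choose(N, n1)` labelings of the midranks (guarded to small samples) and
  returns `2 * min(lower tail, upper tail)` capped at 1.
* `kruskal_wallis()` — H on midranks divided by the tie-correction factor
  `1 - sum(t^3 - t)/(N^3 - N)`, p from the chi-squared law with k-1 df. For
  two groups H equals the square of the tie-corrected Mann–Whitney z.
* `pairwise_compare()` — all pairwise Mann–Whitney tests with Bonferroni
  thresholding: significance at `alpha/m` (0.05/3 = 0.0167 in the standard
  three-group design). Raw p-values are reported; only the threshold is
  adjusted, and no adjustment is made across the three metrics.

Groups backed by fewer than three specimens are summarized but excluded
from hypothesis tests with a warning, mirroring standard practice for
two-specimen cells.

The asymptotic and exact routes agree to within 0.005 where decisions are
made (exact p at or below 0.05); in the middle of the null distribution the
no-continuity approximation is anticonservative by up to ~0.05, which is a
property of the method being reproduced, not an implementation artifact.

## The synthetic specimen generator

No public digitized-cadaver data exist for this protocol, so the package
ships a generator that emulates the digitization study design end to end and
makes every stage testable. `generate_cohort()` produces the standard
design: four specimens per tear category, each with two regions, nine
dissection layers per region (three per part, 1.5 mm apart), 10–60 bundles
per layer and 10–20 digitized sites per bundle with isotropic Gaussian
digitizer noise (SD 0.02 cm).

Each fascicle is constructed analytically before digitization: a
constant-speed planar curve of exact arc length `L` whose in-plane tangent
angle follows a smoothstep profile — flat over the terminal 15% of arc
length at each end, turning in the middle. The plateau makes the configured
end angles exact ground truth for the tangent-averaging measurement (whose
window, 10%, sits inside the plateau), while the mid-curve turn gives a
realistic 1–3% arc/chord excess so that spline fitting and arc-length
quadrature are genuinely exercised. Anterior bundles attach onto the
anterior tendon axis (penniform convergence); posterior bundles run
near-parallel with laterally spread attachments (fusiform). Category-C
specimens lack a posterior region with probability 0.5, reflecting the
observed absence in half of the heavily retracted specimens.

Per-cell targets default to the published per-part medians; dispersions are
log-normal for FBL (`sigma_log = 0.25`; the log-normal median equals the
target regardless of spread) and folded-normal on [0, 90] degrees for
pennation (`sd = 7` degrees; the folded median is within ~0.2 degrees of the
location for these targets). These dispersions were chosen so that the
sample median of a ~400-bundle cell has enough precision for the pipeline's
stated recovery tolerances (5% FBL, 2 degrees PA) while the generated
min–max spans remain of the same order as the published ranges; the
published extreme values (e.g. pennation maxima near 90 degrees) have
heavier tails than a folded normal and are not reproduced.

Randomness is organized as named sub-streams: a Lehmer-style label hash
(exact in double precision) derives one seed per specimen and per
dissection layer, and bundles draw sequentially within their layer stream —
so enlarging a layer appends bundles without perturbing existing ones, and
specimens are independent. Tear records follow the category definitions,
with diameters drawn log-normally around the published category medians and
the tear boundary emitted as an ellipse in the tendon plane whose projected
caliper diameters equal the drawn values exactly.

What the generator does *not* emulate: between-cadaver variance components
(not reported anywhere for this protocol; the generator draws all bundles of
a cell from one distribution), fat infiltration and atrophy, curvature of
the tendon axis, anatomically realistic attachment footprints, and
digitizer failure modes such as missed sites or swapped orderings. Passing
recovery tests therefore demonstrates correctness of the measurement
pipeline under the stated noise model, not robustness to every property of
real cadaveric data.

## Numerical choices and degenerate inputs

* Fascicles need at least 4 points; consecutive duplicate points are
  rejected naming the offending index. Counts outside 10–20 warn but pass.
* Arc-length inversion uses linear interpolation on the dense table;
  endpoint samples are snapped to the digitized endpoints.
* Tangents are central differences on the spline at 1e-6 of the knot span.
* `pennation_angle` clamps the cosine into [-1, 1] before `acos`.
* A tendon axis with all points coincident, landmarks collinear, or an
  empty group in a test are hard errors; a tear boundary degenerate after
  projection is a warning with zero diameter.
* Exact Mann–Whitney refuses enumerations beyond 2e5 labelings rather than
  silently taking minutes.

Problem sizes used by the test suite were chosen to keep the full suite in
the minutes range while leaving the statistical checks sharp: the recovery
tests run one full default cohort (~7000 bundles, about 2–3 minutes); the
exact-test null-calibration property runs at n = 8 per group with the exact
p memoized by the observed U (p depends on the data only through U for
untied samples), 2000 replicates.

## Known limitations

* Pooling bundles across specimens ignores within-specimen correlation;
  p-values for architecture comparisons are anticonservative to an unknown
  degree. A mixed-model extension is out of scope.
* The anatomical-plane convention for tear measurement is a reconstruction,
  not the original caliper procedure.
* The interpolating spline cannot reduce digitizer noise: the arc-length
  noise floor is ~`2 sigma^2 / h^2` relative (noise SD `sigma`, site
  spacing `h`), about 0.3% at the default 0.02 cm noise but ~2.5% if noise
  reaches 0.05 cm. Smoothing splines are deliberately excluded to stay
  faithful to the interpolating-spline definition of FBL.
* Tendon outlines are carried through to OBJ export for visualization only;
  the line of force is a single axis per region, not depth-resolved.
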