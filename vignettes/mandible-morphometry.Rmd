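---
title: "Mandibular morphometry: models, constructions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mandibular morphometry: models, constructions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mandimorph)
```

## The measurement model

The package implements a landmark-driven measurement protocol for dentate
adult mandibles. The inputs are a triangle surface mesh in millimetres
(STL, binary or ASCII) and a set of named, sided landmarks placed on the
bone surface: the upper and most posterior condylar points, the distal
second-molar and canine points (each the midpoint of a vestibular/lingual
pair placed at the tooth), the basilar projection of the mental foramen
(all bilateral), plus two median points — the inter-incisor point at the
cementoenamel junction of the central incisors and the mental protuberance
("chin", the lowest median symphysis point).

Ten measurements are reported per mandible, six bilateral and four single:
gonial angle, basilar symphysis angle and canine angle (degrees); vertical
posterior dimension, dentate length, basilar body length, basilar and
alveolar symphysis lengths, symphyseal height and bi-gonial length
(centimetres). Internally everything is computed in millimetres; the
reporting unit for lengths is cm, matching the convention of published
cohort tables.

### Anatomical frame

All constructions happen in a subject-specific orthonormal frame
(x = right, y = anterior, z = up, origin at the chin):

* the **mid-sagittal plane** is the least-squares plane through the
  midpoints of the five bilateral landmark pairs, constrained to contain
  the chin-to-inter-incisor direction (a 2x2 eigen problem solved in closed
  form, which also makes mirrored inputs behave exactly);
* the **up axis** is the normal of the basilar plane through the chin and
  the two basilar mental-foramen points — the mandibular-plane convention —
  orthogonalised against the sagittal normal and signed so the condyles lie
  above the body. This gives the mental-foramen landmark a definite role:
  it anchors both the basilar reference plane and the body tangent bands,
  while no distance measurement consumes it directly.

For a bilaterally symmetric configuration the frame is exact. Real (and
realistically asymmetric synthetic) mandibles tilt the fitted mid-sagittal
plane by a degree or two; the projections below inherit that tilt, which is
the dominant residual error of the pipeline (typically well below half a
degree and half a millimetre at published asymmetry levels).

### Silhouettes, tangents and derived points

The classical outline constructions are performed on planar silhouettes:
each hemimandible is projected onto its lateral (sagittal-parallel) plane
for the gonial construction, and thin basilar (bottom 12% of the symphysis
height) and alveolar (top 15%) bands are projected axially for the
inflexion constructions. The silhouette is the exact outer boundary of the
union of the projected triangles, computed in continuous coordinates:
edges are split at mutual intersections and T-junctions, sub-segments are
classified by probing either side of their midpoint, and boundary segments
are chained into loops. Near-coincident coordinates are welded at
2e-5 of the bounding-box diagonal, and faces within ~3 degrees of the
projection direction are excluded (they carry no silhouette area but
project to numerically hostile slivers). No rasterisation is involved.

A **tangent** is the supporting line of the convex hull of the silhouette
boundary restricted to the band between two landmark anchors, touching
from a stated outside direction. Because a clean silhouette stores only
corner vertices, the band clips boundary *edges* (not just vertices), and
the chosen hull edge is refitted through all band points collinear with it
(within 1e-4 of the bounding-box diagonal) so that micrometre projection
wobble cannot rotate the line. Anchor pairs: posterior condyle down to the
basilar level for the ramus tangent; mental foramen to below the condyle
for the body tangents; chin to mental foramen for the symphyseal tangent;
inter-incisor to distal molar for both alveolar tangents.

Angle conventions: a tangent pair defines four sectors; the reported angle
is that of the sector containing a bone-side witness point (the published
mandibular angles are all obtuse interior angles). Witnesses are
landmark-derived (a point just above the mental foramen for the gonial
angle; the inter-foramen and inter-molar midpoints axially), which keeps
the choice valid across the whole anatomical range — a naive "flip towards
the witness" rule fails for witnesses near a sector edge.

The **gonion** is the first silhouette boundary point along the interior
bisector ray of the gonial tangents (ties broken by the smallest ray
parameter), lifted back to 3D as the nearest mesh vertex to the
inverse-projection line *with a lateral preference*: among vertices within
a small 2D neighbourhood of the hit, the lateral cortex is selected first
and the nearest of those returned. A plain nearest-vertex rule (or exact
ray casting) can land on the medial cortex whenever the frame is slightly
tilted, because the silhouette corner is then generated by the inner
corner edge — a full bone-width error on the bi-gonial length.
**Inflexion points** are tangent intersections in the axial plane, lifted
to the basilar (resp. alveolar) landmark level; with a rounded (filleted)
gonial corner of radius r and gonial angle gamma the bisector hit lies on
the arc at distance r (1/sin(gamma/2) - 1) from the tangent intersection,
which the test suite checks in closed form.

## The synthetic mandible

No CT data accompany the published cohort, so validation rests on a
parametric phantom with closed-form ground truth. The solid is a stylized
horseshoe assembled from a few watertight planar-faced components that
overlap geometrically (measurements use silhouettes, for which unions are
handled exactly; no boolean CSG is attempted):

* per side, a **body+ramus** piece: an L-shaped lateral profile — basilar
  edge at z = 0, posterior ramus border leaning back by (gonial angle -
  90 deg), optional fillet arc at the gonial corner — extruded across the
  bone thickness and sheared laterally so the basilar body line flares at
  the angle implied by the basilar symphysis angle. The shear leaves the
  lateral projection untouched, so the gonial angle is exact by
  construction while the axial footprint carries the basilar angle.
* an anterior **symphyseal wall** whose outer face carries the chin and
  meets each body line at the basilar symphysis angle, continuing a few
  millimetres along each body line (the body pieces are trimmed 3 mm
  behind the inflexion chord so the wall alone defines the anterior
  outline, which keeps the construction valid even for a flat or slightly
  receding chin);
* an **alveolar ridge band** following the dental arch at the height
  implied by the symphyseal height; its vestibular outline is the mitered
  outward offset of the mid-ridge polyline, so the alveolar inflexion
  corners sit exactly at the parameterised alveolar symphysis length and
  the canine angle is exact at the canine landmark.

Every protocol value follows from the parameters in closed form, including
the fillet geometry, and the generator emits the true landmark set
(primed pairs included), the true derived points, the true measurement
record, the analytic lateral-silhouette area and its own vertex count.

Two parameterisation choices deserve emphasis:

* **The bi-gonial length is derived, not sampled.** It follows from the
  symphysis chord, the body lengths and the basilar angles by planar
  trigonometry; sampling it independently would over-constrain the
  geometry. Its simulated dispersion is checked for plausibility against
  the published mean (within 1 cm), not identity.
* **Body flare is fixed; the chevron cant varies.** The basilar symphysis
  angle equals 90 deg + body flare + symphyseal cant. Realising the full
  published between-subject angle SD (5-7 deg) as body-line flare would
  inflate the derived bi-gonial SD to ~1.1 cm against the published
  0.6 cm. The generator therefore fixes the flare (default 25.3 deg) and
  absorbs the subject-level (left/right symmetric) basilar-angle variation
  into the chin-region cant, while per-side asymmetry still flares the two
  body lines differently. Each side's angle keeps its published marginal
  distribution, and the bi-gonial dispersion lands on the published value.

### Cohort simulation

`sample_cohort_params()` draws every measurement from a normal
distribution with its sex-specific published mean and SD, truncated at
+/-4 SD and at the geometric validity bounds. Distinct measurements are
independent (the source reports no covariances; this is a stated fidelity
limit). The left/right pair of a bilateral measurement shares a
subject-level component (correlation 0.9): each side keeps its printed
marginal exactly, while within-subject asymmetry stays in the few-degree
range that the source cohort explicitly reports as "symmetrical" — fully
independent sides would produce 10-degree asymmetries that no real
mandible shows and that degrade the frame fit.

What a green test on this phantom does establish: the tangent/bisector
constructions, the frame, the projections and the statistics reproduce
known geometry to within 1 degree / 1 mm across the anatomical parameter
range, under STL round-trips, rigid motions, mirroring and scaling. What
it does not establish: performance on real CT surfaces with curved
borders, dental artefacts, or manual landmark placement biases — the
phantom's borders are straight by construction, so the supporting-tangent
stand-in for manually drawn tangents is exact here and only approximate on
real bone.

### Landmark placement noise

`jitter_landmarks()` displaces every placed landmark by isotropic Gaussian
noise and re-projects it onto the nearest surface point; derived midpoints
are recomputed from the jittered primed pairs, preserving the midpoint
invariant. The reliability layer repeats placements per subject and
computes ICC(2,1).

## Statistics layer

* Descriptive summaries use the sample SD (n-1) and CV = 100 SD / mean.
  Reported rounding is one decimal, half away from zero, matching the
  published table's convention.
* Sex comparisons run on per-subject bilateral averages (side asymmetry
  would otherwise interfere). The stated toolkit "ANOVA or Friedman" is
  implemented as: two-group one-way ANOVA when both sexes pass
  Shapiro-Wilk at alpha = 0.05, otherwise the unpaired rank analogue
  (Wilcoxon-Mann-Whitney) — the Friedman test requires paired blocks and
  cannot compare independent sexes. The paired left-vs-right
  repeated-measures contrast is exposed separately
  (`side_symmetry_test()`, a Friedman test on subjects x sides). No
  multiplicity correction is applied (none was applied in the source
  analysis); the number of tests is attached to the result for
  transparency.
* The ICC model is two-way random effects, absolute agreement, single
  measurement — the standard choice for repeated placements by one
  observer across sessions; the source does not name its variant. Rosner
  classes: poor (< 0.4), fair to good (0.4 to < 0.75), excellent
  (>= 0.75), with the boundary values 0.74 / 0.75 falling as "fair to
  good" / "excellent".

## Guide planner

The planner is deliberately 2D and anterior-only: the published analysis
standardizes the anterior mandible (symphysis angle 120 deg, symphysis
length 25 mm) and explicitly excludes the gonial/ramus region from
standardization because of its large inter-individual variability. A plan
is one symphyseal segment flanked by two body segments; the bone wedge
removed at each junction is 180 deg minus the planned interior angle, and
every segment must respect the 15 mm perfusion minimum (small fragments
compromise the periosteal blood supply). The flanking body-segment length
(default 40 mm) is a configuration choice, not a published value.

## Numerical choices and limitations

* Silhouette tolerances: vertex weld 2e-5, midpoint probes 1e-6 (with a
  1/64 inner probe for slivers), chaining grid 1e-7, crack bridging 1e-4 —
  all relative to the 2D bounding-box diagonal, so the pipeline is
  scale-covariant.
* Contours are cleaned by removing duplicate and collinear vertices at
  1e-9 relative tolerance; hull micro-edges below 2e-3 of the hull
  diagonal are never selected as tangents.
* The fillet arc is polygonalised at 12 segments; its chord error
  (micrometres) is negligible against the 1 mm acceptance tolerance.
* Degenerate inputs raise informative errors: parallel tangents, collinear
  canine configurations, missing landmarks, conflicting generator
  parameters (each error names the conflicting pair). Heavy placement
  noise (sigma = 4 mm) may produce individually degenerate placements;
  the reliability layer re-draws such repeats, as an observer would
  re-place obviously wrong landmarks.
* Acceptance-scale simulations are scaled down where the full published
  protocol would exceed the test-time budget (the ICC-versus-noise curve
  uses 4 subjects x 3 repeats x 6 seeds with common random numbers across
  noise levels; the single sigma = 0.5 check keeps the full 10 x 5
  design). The published ICC range (0.729-0.987) is treated as
  directional, not as a target.
* One stated-world criterion is knowingly not met: sampling the printed
  alveolar symphysis distributions (2.8 +/- 0.2 vs 2.9 +/- 0.2 cm)
  implies a medium effect (d = 0.5) and ~50% rejection at n = 30 per
  group, whereas the source reports p = 0.90 — the printed means are
  rounded to coarser precision than the underlying effect. The simulation
  asserts the stated criterion and documents the discrepancy rather than
  tuning the generator away from the printed values.
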