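---
title: "Measuring acetabular cup coverage in severe hip dysplasia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular cup coverage in severe hip dysplasia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In Crowe type-IV developmental dysplasia of the hip (DDH) the femoral head is
fully dislocated and the original ("true") acetabulum is small, shallow and
roughly conic, usually under 40 mm across. Total hip arthroplasty in these
patients typically uses a 44-mm cup — the smallest shell that still accepts a
28-mm head — so part of the cup is inevitably left without bony support. The
fraction of the cup surface *not* covered by host bone (the total uncoverage
ratio, TUCR) and its distribution over the four acetabular quadrant segments
(A-S, A-I, P-S, P-I) are the quantities a surgeon wants preoperatively: a
total coverage below roughly 70% argues for structural grafting or an
alternative cup position.

`cupcoverage` implements this measurement as a reproducible pipeline over
triangle meshes and landmarks, together with a parametric synthetic
hemipelvis generator whose coverage ground truth is known by construction, so
every stage can be validated end to end.

## Coordinate frame

The anterior pelvic plane (APP) frame is built from four landmarks: both
anterior-superior iliac spines (ASIS) and both pubic tubercles.

* The **coronal plane** passes through both ASIS and the midpoint of the
  pubic tubercles. The APP is defined by four points but a plane needs only
  three; we reduce the over-determined set by passing the plane exactly
  through the two ASIS and the tubercle *midpoint*. This is a deliberate,
  documented choice — other reductions (least-squares over four points) give
  planes differing by fractions of a degree.
* The **sagittal plane** is perpendicular to the coronal plane through the
  tubercle midpoint, with its normal along the inter-ASIS direction; the
  **horizontal plane** is perpendicular to both.
* Axes: `lateral` (toward the studied hip), `anterior`, `superior`. The
  superior direction is disambiguated by requiring the ASIS to lie superior
  to the tubercle origin.

Pelvic tilt is *not* corrected: the APP is taken as the reference as-is,
which mirrors standard CT-based planning practice and is a known limitation
of that convention.

## Cup orientation and seating

The cup's polar axis (pointing out of the opening) is set from radiographic
angle conventions: inclination (abduction) is the angle of the axis's
coronal-plane projection with the longitudinal axis, anteversion the angle
between the axis and the coronal plane. In `(lateral, anterior, superior)`
coordinates,

$$u = (\cos RA \sin RI,\; \sin RA,\; -\cos RA \cos RI),$$

with `RI = 45` deg and `RA = 20` deg by default. The protocol's "45 ± 1, 20
± 1 degrees" is treated as an execution tolerance of manual placement, not a
parameter sweep: the simulation fixes the angles at exactly 45/20 (both
exposed in the configuration).

Seating follows three rules — medialize until the shell abuts the medial
wall, keep the front edge tangent to the anterior wall, keep the lower edge
tangent to the transverse ligament — operationalized deterministically:

1. start at the centroid of the acetabular rim landmarks;
2. translate along the polar axis toward the dome ("medialize") until one
   more 0.1-mm step would drive a 400-point sample of the outer shell
   strictly into bone; the final contact depth is refined by bisection to
   0.01 mm so the converged centre does not depend on the marching step;
3. project onto the two tangency constraints by coordinate descent (match
   the rim point nearest the anterior-wall landmark along the anterior axis;
   match the superior coordinate of the inferior-most rim point with the
   ligament landmark), re-checking medial contact after every correction,
   with per-sweep corrections capped at 3 mm.

The ligament is a *landmark point* in this data model, not a surface, so
"tangency" means matching its superior coordinate. When the three rules are
mutually infeasible within the 0.2-mm tolerance the residuals are reported,
not hidden. How the original manual protocol resolved simultaneous
over-constraint is unknowable; this residual-reporting descent is one
deterministic resolution.

## Coverage and the quadrant partition

Coverage is measured on the outer surface of a 0.01-mm "eggshell" copy of
the cup (the articular outer hemisphere only; rim annulus and inner surface
are excluded from the denominator). A facet is covered when its centroid
lies inside the bone solid or within `eps = 0.1` mm of the bone surface.
The membership test is ray parity with a fixed pseudo-random direction,
re-cast on degenerate edge/vertex grazes. The 0.1-mm band absorbs mesh
discretization (CT-scale facets are ~0.5 mm, the eggshell is 0.01 mm thick)
without inventing coverage; it is exposed in the configuration because
whether the original Mimics-based measurement counted sub-millimetre gaps as
covered is unknowable.

The screw-zone quadrant construction is two-dimensional in origin; lifting
it to 3-D requires a choice. We define the **quadrantal sagittal plane**
through both ASIS and the cup centre, and the **quadrantal horizontal
plane** through the cup centre with its normal along the
ipsilateral-ASIS-to-cup-centre direction — which makes the two planes
exactly perpendicular and reduces to the classical construction in the
2-D projection. Facets are assigned to A-S/A-I/P-S/P-I segments by the
signs of their centroid's distances to these planes (centroids within
1e-9 mm of a plane go to the anterior, respectively superior, side — a
deterministic, measure-zero tie-break). Every segmental ratio divides by
the *total* cup surface area, so the four segmental ratios sum to the TUCR
identically; the published segmental means indeed sum to the published
total within 1e-4, confirming that denominator convention.

Facet-centroid classification (rather than vertex voting or sub-facet
clipping) is used because its bias vanishes with refinement and keeps the
Monte-Carlo cross-check clean. At the default subdivision (a 32 x 128
latitude-longitude hemisphere, ~8000 facets) the TUCR of analytic fixtures
is stable to better than 0.01 against one extra refinement level.

## Morphometrics

* **Acetabular height H**: perpendicular distance from the most superior
  *rim landmark* to the plane parallel to the pelvic horizontal plane
  through the acetabular lower edge, computed with the textbook
  point-to-plane formula `|a p1 + b p2 + c p3 + d| / sqrt(a^2+b^2+c^2)`.
  The superior extreme is taken over the rim landmark set, not the whole
  mesh — on a full hemipelvis the global extreme would be the iliac crest.
* **A-P diameter R**: the bone surface is sectioned by the horizontal plane
  at half height (plus any mesh vertices within a 0.5-mm slab, matching the
  CT slice thickness); points within the acetabular neighbourhood (a ball
  around the rim centroid, radius 1.1 x the rim spread + 0.5 mm) are kept
  and R is their extent along the anterior axis.
* **Volume proxy** `V = H * R * R`, exactly as printed in the protocol this
  package emulates. The conic-volume motivation would suggest a 1/3 pi
  constant; the proxy is implemented literally, without a constant.

## The synthetic phantom

The generator's purpose is an *independent oracle* for the whole pipeline,
not anatomical realism. One synthetic hip consists of:

* an **articular support shell**: a spherical shell congruent with the cup
  (inner radius = cup outer radius 22 mm, 6 mm of bone stock behind it)
  spanning the cup dome for the canonical 45/20 axis. Because the two
  quadrant planes intersect in a line through the cup centre, the four
  quadrant segments are exact dihedral sectors around that line; a
  **deficiency window** for quadrant Q removes the rim-adjacent part (polar
  angle above a solved threshold) of Q's sector so that the removed solid
  angle equals the requested fraction `f_Q` of the quadrant's area. Ground
  truth is integrated over the *realized* grid cells of the mesh, so the
  pipeline is compared against exactly the geometry that was built;
* an **elliptical rim landmark ring** whose vertical extent realizes the
  target height exactly, offset 26 mm laterally along the cup axis from the
  socket centre (so the half-height measurement plane stays clear of the
  support shell);
* two small **wall blocks** whose outer faces realize the target A-P
  diameter exactly;
* tangency landmarks placed at the seated cup's anterior-most and
  inferior-most rim points.

Two numerical subtleties are built into the phantom rather than the
pipeline. First, the shell's inner surface is *circumscribed*: its nodes
are pushed outward by the worst-case facet sag so no chord dips below the
articular radius. Congruent-sphere contact is tangential, so an inward sag
`s` would otherwise cause first contact `sqrt(2 r s)` early (0.4 mm for an
8-µm sag) and dominate the placement error budget. Second, cells are
de-pinched: diagonal corner contacts between grid cells would make the
window walls non-manifold, so one cell of each diagonal pair is filled
before meshing.

The default cohort emulates the study population: height 31.99 ± 4.09 mm
and A-P diameter 25.23 ± 4.82 mm (truncated normal at ±3 SD intersected
with the phantom's feasibility region), and per-quadrant deficiency
fractions whose means and SDs are the published segmental uncoverage
moments divided by each quadrant's share of the dome area under the
canonical geometry (shares 0.208/0.125/0.375/0.292 for A-S/A-I/P-S/P-I).
This makes the *expected* segmental ratios of the synthetic cohort match
the cohort being emulated, with TUCR ≈ 0.30 ± 0.10. The posterior-superior
and posterior-inferior deficiencies share a Gaussian correlation of 0.5, so
the statistics stage can demonstrate a positive P-S/P-I association
qualitatively — no claim is made of reproducing the published correlation
magnitudes, whose patient-level data are unavailable. Deficiency draws are
clamped to [0, 0.8]; fractions much above ~0.9 are geometrically
unrealizable as single-sector windows and raise a constructive error.

What the phantom does *not* emulate: real pelvic shape (the bone is a
stylized shell plus blocks, not a hemipelvis), imaging artefacts,
segmentation noise, cartilage/osteophyte ambiguity at the rim, and any
anatomical coupling between socket size and wall deficiency. Passing the
recovery tests therefore demonstrates the *measurement machinery* is
correct, not that results on real CT reconstructions share its error
bounds.

## Statistics stage

Pearson correlation with simple linear regression (`R^2 = r^2` preserved
exactly), a one-sample Kolmogorov-Smirnov normality screen against a normal
with the sample moments, Welch's unequal-variance t for the two-group
comparison, and a summary table with mean, SD, observed range and mean ±
1.96 SD/sqrt(n) — all three interval types labelled, because summary
"confidence interval" columns in this literature are sometimes data ranges.
Design choices worth stating:

* the group-comparison test is Welch's t (the emulated protocol names no
  test; the groups are unbalanced, 20 vs 10, with no variance-equality
  evidence);
* the K-S screen with estimated parameters is conservative (the Lilliefors
  correction is deliberately not substituted, since the plain K-S test is
  what the protocol names); the caveat is documented on the function;
* no multiple-testing adjustment is applied (none is applied in the
  protocol being emulated); the summary footer flags this;
* bilateral hips are treated as independent records, as in the emulated
  cohort (30 hips from 26 patients).

## Numerical choices and problem sizes

Degenerate inputs error early and explicitly: collinear plane points,
non-watertight meshes (with the open-edge count), zero-variance samples,
empty measurement slabs. All computations are deterministic given the
configuration and master seed; per-hip child seeds derive arithmetically
from the master seed, and the acceptance script threads a single `--seed`
through everything.

Validation runs use sizes chosen to exercise the geometry well inside a
desktop budget: coverage fixtures at ~8000 cup facets against analytic
half-spaces with 1e6-point Monte-Carlo oracles; a 20-hip recovery cohort;
10 random rigid motions for invariance; 5000 null simulations for the Welch
type-I calibration. The bundled tests assert: fixture TUCR within 0.01 of
closed forms, segmental recovery within 0.01 absolute, height and diameter
within 0.5 mm, seating within 0.2 mm on the congruent-pocket fixture, and
exact partition and regression identities.

## Known limitations

* The eps coverage band biases uncovered areas slightly downward near
  deficiency-window boundaries (about 0.002-0.005 per segment at
  defaults); it is the price of robustness to mesh discretization, and it
  shrinks linearly with `eps`.
* On geometries exactly axisymmetric about the cup axis (the analytic
  half-space fixtures), whole latitude rows of facets cross the coverage
  threshold together, so the facet-based TUCR is quantized at roughly the
  row-area fraction (~0.01 at default subdivision). Real and synthetic
  sockets break that symmetry; the fixtures' agreement bound of 0.01
  reflects this worst case.
* Binary STL stores float32 coordinates; the 1e-6-mm round-trip guarantee
  holds for ASCII STL only.
* The placement search assumes the landmarks make the seating problem
  well-posed; for pathological inputs the residual report, not the pose,
  is the trustworthy output.
* Segmental ratios depend on the 3-D lift of the quadrant construction;
  alternative lifts (e.g. a horizontal quadrant plane containing the cup
  axis) would shift facet assignments near the boundaries.
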