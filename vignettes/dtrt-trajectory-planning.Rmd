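---
title: "Geometry-based trajectory planning for dynamic trajectory radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-based trajectory planning for dynamic trajectory radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtrtplan)
```

## The planning problem

Dynamic trajectory radiotherapy (DTRT) delivers radiation while the
gantry, table (couch) and collimator all rotate. Compared with coplanar
VMAT, the extra degrees of freedom let the beam approach the target from
non-coplanar directions that avoid shining through organs at risk (OARs).
The geometric planning problem solved here is: *given voxelized target and
OAR masks, find table and collimator trajectories over a full gantry
rotation that minimize geometric target/OAR overlap, avoid collisions and
un-scanned anatomy, and respect the machine's kinematic limits.* Dose
optimization (fluence/MLC sequencing) is deliberately out of scope: the
trajectories produced here are the *inputs* to a downstream intensity
optimizer, and the package's metrics modules evaluate whatever dose such
an optimizer produces.

## Coordinate and machine conventions

All geometry lives in a fixed patient frame: +x patient-left, +y anterior,
+z superior, millimetres, isocenter at the origin. Machine angles follow an
IEC 61217-style convention: at gantry 0°/table 0° the source is anterior
and the beam travels along (0, −1, 0); the gantry rotates about +z, the
table about the vertical +y axis through the isocenter, composed
table-then-gantry. Gantry angles are half-open in [0, 360), table angles in
[−90, 90], collimator angles circular in [−180, 180). All of this is
documented once in `?beam_geometry` and `?structure_volume` and used
everywhere unchanged.

## The gantry–table cost map

For one OAR, the cost at (gantry, table) is the fraction of OAR voxels
whose beam's-eye-view (BEV) projection — a divergent point-source
projection onto the isocenter plane, magnification SAD/depth — lands
inside the target's BEV footprint. Two numerical choices matter:

* **Footprint rasterization.** The target footprint is rasterized at 1 mm
  (configurable). Each projected voxel centre stamps a neighbourhood of
  ⌈spacing/2⌉ cells so that a mask sampled at 2 mm still yields a filled
  footprint. The stamp makes the footprint conservative by up to about one
  voxel at the rim; tests therefore compare against brute-force oracles
  that bracket the footprint between its 1 mm and 2 mm Chebyshev
  dilations rather than an idealized outline.
* **Depth weighting.** An OAR voxel upstream of the target (closer to the
  source than the target's median projected depth) shadows the target and
  gets weight 1.0; a downstream voxel only receives exit dose and gets
  0.5. The exact weighting used in clinical in-house systems is not
  published; both weights are exposed as configuration
  (`depth_weights`), and with weights (1, 1) the measure reduces to the
  plain fractional overlap used by the geometric test oracles. The median
  was chosen as the depth reference because it is robust to target shape.

Per-OAR layers are combined as a weighted sum normalized by the sum of the
weights. Normalization keeps combined costs in [0, 1] and comparable
across OAR recipes; it does not change the argmin path for fixed weights,
so this choice is cosmetic for planning and is documented rather than
load-bearing. OAR maps within one recipe are equally weighted by default.

## Exclusion zones

Two mechanisms mark (gantry, table) cells as forbidden:

* **Collision model.** Instead of a mesh-based virtual linac, an analytic
  stand-in: the gantry head is an arc of a ring about the gantry rotation
  axis (default clearance radius 400 mm, longitudinal half-extent 300 mm,
  azimuthal half-extent 30°) and the patient + table is an axis-aligned box
  sampled along its edges at 10 mm. A 2 cm safety margin is applied *to
  each component*, so a point collides when its radial distance reaches
  `clearance − 2·margin` while inside the (margin-inflated) head slab and
  arc. The numbers are plausible C-arm values, not measurements of a
  specific machine; they are configuration, and the model's correctness is
  established by properties (margin monotonicity, collision-free coplanar
  row, hand-computable point cases) rather than by comparison to any
  specific treatment room.
* **CT-scan-length restriction.** A beam must not irradiate through
  anatomy that was never scanned. A cell is excluded when any ray from the
  source to a corner of the target's bounding box crosses the inferior or
  superior CT boundary plane at a point still inside the patient's body
  cross-section (an x/y half-width pair on the envelope, default
  100 × 120 mm). A limitation follows from assuming the body extends
  indefinitely beyond the scan: a beam *exactly* parallel to the
  cranio-caudal axis is always excluded no matter how long the scan, which
  is conservative and, for table angles within ±60°, vanishes as the scan
  lengthens (a property the tests check).

Both causes are retained per cell (`"collision"`, `"ct"`, `"both"`) so GT
maps can be rendered with the conventional light/dark grey shading.

## Path-finding

The search graph is columnar: one node per (gantry control point, table
angle sample), edges between consecutive gantry columns whose table change
satisfies the gradient limit (3° of table per degree of gantry; at the 2°
control-point spacing this is 6° per step). The path cost is the sum of
entered cell costs; excluded cells are untraversable. The A\* heuristic is
zero — i.e. Dijkstra — because at map sizes of 181 × 91 optimality
guarantees matter more than speed, and the optimality is exactly what the
test suite verifies (exhaustive dynamic programming on random maps must
agree bit-for-bit). Start and end table angles are free.

Ties between equal-cost paths are broken deterministically: least total
table travel first, then smallest summed |table angle| (the package
prefers the coplanar arc when nothing is gained by leaving it), then node
index. The same solver runs the collimator search with a circular axis and
shortest-signed-difference steps; field widths are 180°-periodic in
collimator angle, which the width map inherits automatically from the
projection geometry. An optional forced start angle supports plans that
pin the initial collimator.

**Smoothing.** Trajectories are smoothed with a centred moving average to
avoid abrupt table motion. The nominal 10-point (20°) window is even; a
centred even window does not exist, so the implementation uses the
symmetric window of half-width ⌊w/2⌋ (11 points in the interior for
w = 10), shrinking symmetrically at the sequence ends. This preserves two
contracts the tests rely on: output length equals input length, and the
maximum absolute per-step increment never increases (the moving average is
a contraction on increments, including at the shrinking ends). Smoothing
can push a point into an exclusion cell; the point is then projected to the
nearest feasible table angle in its column, clamped to the gradient limit
relative to its neighbours, and the whole path re-validated. Re-checking
*after* smoothing (rather than smoothing last) was an open choice; checking
last is safer and is what this package does.

**Duplication.** A planned path can be expanded into two deliverable
trajectories: *split-field* (SF) fits the secondary jaws so the two copies
partition the target's BEV x-extent at its midpoint with a configurable
5 mm overlap at the junction; *collimator offset* (CRot) adds a copy with a
constant +90° collimator offset and re-fitted jaws. Both mirror standard
clinical practice for large fields and for decoupling leaf-travel
directions between arcs.

**Deliverability.** A separate check verifies that with the gantry at its
maximum speed (default 6°/s) no axis must exceed its own speed limit
(defaults 20°/s for table and collimator — deliberately generous,
config-level values) between consecutive control points.

## Plan-quality metrics

DVHs are computed over structure voxels (volume = voxel count × voxel
volume), with dose resampled trilinearly onto the structure grid when the
grids differ (clinically: 2.5 mm dose vs 2 mm CT). D_x% interpolates
linearly between the bracketing order statistics of the voxel doses — the
value is tolerance-sensitive, so the interpolation rule is part of the
documented contract and the tests only assert values inside the bracketing
order statistics. D_0.03cc accumulates the hottest voxels by volume and
interpolates within the voxel where the cumulative volume crosses 0.03 cm³.
Normalization scales the entire distribution by one factor (D95% → 100% of
prescription, or D97% → 99% for stereotactic-style prescriptions) and is
idempotent. CI_Paddick = TV_PIV²/(TV·PIV) and HI₉₅% = V₉₅% − V₁₀₅% follow
their standard definitions; V_x thresholds are relative to the
prescription of the individual dose level.

## Gamma analysis

Global gamma with dose tolerance as a percent of the *reference*
distribution's maximum (the convention when one distribution is the
measurement standard; stated explicitly because "percent of maximum dose"
is ambiguous in common usage), distance-to-agreement in mm, and a low-dose
threshold that removes points from the passing-rate denominator. The
evaluated distribution is interpolated bilinearly on a sub-grid of
0.1·DTA within a search radius of 3·DTA — a standard
accuracy/cost trade-off: finer sub-sampling changes rates by far less than
the 0.5-percentage-point agreement demanded of the independent brute-force
oracle, while a 3·DTA cap bounds the search (γ values above 3 are reported
as found but are already deep failures). Grid-origin offsets between
reference and evaluated are folded into the search shift.

## The synthetic world

`hn_phantom_spec()` builds the default head-and-neck-like phantom: a 25 mm
radius spherical target at the isocenter, two 15 mm "parotid-like" spheres
at ±45 mm laterally, a 5 mm × 120 mm "cord-like" posterior cylinder, and a
90 × 110 × 150 mm body ellipsoid on a 2 mm isotropic grid. The values were
chosen once to create the asymmetric gantry–table cost structure
characteristic of lateralized head-and-neck anatomy — a dominant lateral
OAR plus a serial posterior one — and are not measurements of any real
phantom. Voxel membership is by voxel centre; voxelized volumes converge
to analytic volumes as spacing shrinks (tested at 2 mm vs 1 mm).

Analytic dose modes (uniform, linear gradient in percent of plateau per
mm, spherical plateau-with-falloff) and the delivery-log generator
(`actual = expected − lag_gain · speed + N(0, noise_sd)`, timestamps from
the gantry at maximum speed) exist so that every metric has a case with a
known answer. Defaults (lag 0.05 s-equivalent, noise 0.01°) produce the
qualitative signature seen in real dynamic deliveries — strong negative
speed–deviation correlation for table and collimator — without claiming
any specific machine's numbers.

What a green test does **not** establish: agreement with a commercial
optimizer or dose engine, with film measurement, with a mesh-based
collision model of a specific treatment room, or with any clinical
outcome. The synthetic phantoms have no CT densities, the dose modes are
not transport calculations, and the delivery logs contain no real servo
dynamics beyond first-order lag.

## Runtime choices in the tests

The production defaults sample the GT map at 2° × 2° (181 × 91 cells).
Tests and acceptance checks that build maps from phantoms use coarser
angular sampling (10–24°) to stay inside desk-scale runtime budgets; the
verified properties (weighted-sum algebra, mirror symmetry, A\* vs
dynamic-programming optimality, sparing vs the coplanar arc, exclusion
monotonicity) are resolution-independent. Kinematic-invariant checks always
run at the production 2° control-point spacing with the 3°/° limit, on
randomly generated cost/exclusion structures plus random spherical targets
for jaw fitting.

## Known limitations

* Overlap cost is purely geometric; no fluence, attenuation or
  scatter — by design, matching the geometric-planning scope.
* The collision model is conservative and parametric, not patient- or
  room-specific; absolute exclusion zones will differ from any specific
  installation.
* The axial-beam CT-length conservatism described above.
* Gamma analysis is implemented for planar (film-like) comparisons; 3D
  grids are accepted but the default 0.1·DTA sub-sampling becomes
  expensive in 3D.
* TrueBeam binary log files are not parsed; logs use a documented CSV
  schema, since the analysis — not the proprietary format — is the point.
* Whether speed should derive from expected or actual positions is not
  standardized; expected positions are used.
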