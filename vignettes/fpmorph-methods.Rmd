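---
title: "Measuring femoropopliteal deformation under knee flexion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoropopliteal deformation under knee flexion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmorph)
```

## The measurement problem

The femoropopliteal (FP) axis — the superficial femoral artery (SFA) running
down the thigh and the popliteal artery (PA) crossing the knee — is the most
mobile arterial territory in the body. When the knee flexes from a straight
(180°) to a bent (90°) position, the artery foreshortens and buckles; a
covered stent placed across the knee to exclude a popliteal aneurysm must
survive those cyclic deformations. Quantifying them requires a chain of
geometric operations on segmented CT angiography: registering all
acquisitions of a patient into one reference frame, extracting the vessel
centerline, splitting it into SFA and PA at the adductor hiatus, and
computing per-segment length, tortuosity and mean luminal diameter, plus a
decomposition of PA tortuosity onto anatomical planes.

`fpmorph` implements that chain end to end and — because patient CTA data
cannot be redistributed — validates every stage against synthetic limb
phantoms with analytically known ground truth.

## Metrics

**Length** is the cumulative chord length of the centerline polyline.

**Tortuosity index** is
$$T = \frac{L}{D} - 1,$$
with $L$ the centerline arc length and $D$ the straight-line distance
between its endpoints. A straight vessel has $T = 0$; clinical straight-knee
values for this territory are a few times $10^{-2}$, bent-knee popliteal
values reach $\sim 0.2$. The index is dimensionless and invariant under
rigid motion and uniform scaling, both of which the tests assert. (A
"length times endpoint-distance minus one" reading of the defining formula
would be dimensional and could not reproduce printed values below 1; the
ratio form is the only consistent reading and is the one implemented.)

**Mean diameter** comes from planes perpendicular to the centerline at
5 mm arc-length intervals (a configurable step). Each plane–surface
intersection loop that encloses the centerline point is treated as perfectly
circular, so the equivalent diameter is $D = 2\sqrt{A/\pi}$ from the polygon
area $A$ (shoelace formula); per-segment diameter is the simple average of
the section diameters, not an arc-length-weighted one — matching the
"average of each surface" convention of the measurement protocol the
package models.

**Decomposition.** PA tortuosity is additionally computed on two orthogonal
projections of the centerline. The anatomical frame is derived from the
tibia: its first principal direction is the superior–inferior axis; a
user-supplied anterior hint, orthogonalized against it, gives the
antero-posterior (AP) axis; the medio-lateral axis completes a right-handed
triad. Under the default convention `T_Front` is the tortuosity of the
projection onto span(tibia, AP) — the view that retains AP bowing, which is
what sagittal-plane knee flexion produces — and `T_Lat` of the projection
onto span(tibia, medio-lateral). The opposite reading is one flag away
(`plane_convention = "swapped"`), because the anatomical naming of the two
views is a convention, not a computation. Projected tortuosity uses the
projected chord in the denominator, keeping the index dimensionless and
comparable with the 3D value; projection is 1-Lipschitz, so projected
length never exceeds 3D length (property-tested on 1000 random curves), but
the *ratio* can exceed the 3D ratio, so no `T_plane <= T` inequality is
asserted — it is false in general. The frame is computed per configuration
from that configuration's tibia, so the planes flex with the shank; this
matches the view that "front" and "lateral" are defined relative to the
lower leg in each posture.

## Centerline extraction

Masks are binary voxel volumes with a voxel-to-world affine. Extraction is
a medialness-weighted geodesic:

1. the Euclidean distance transform (EDT) of the foreground is computed by
   the separable lower-envelope algorithm (exact, in mm, compiled code;
   validated against a brute-force oracle on random masks);
2. the two seeds are snapped to their nearest foreground voxels and joined
   by a shortest path on the 26-connected voxel graph with edge cost
   $\ell \cdot \tfrac12(1/(d_u+\varepsilon) + 1/(d_v+\varepsilon))$, where
   $\ell$ is the step length, $d$ the EDT value and
   $\varepsilon = 0.1\,h$ for spacing $h$ — cheap to traverse near the
   lumen axis, expensive near the wall;
3. each path point is then moved to the local medial position by iterated
   gradient ascent on the trilinearly interpolated EDT, with the ascent
   direction projected onto the plane perpendicular to the local path
   tangent.

The tangential restriction in step 3 matters: near the vessel ends the
distance field is governed by the end caps and an unrestricted ascent
drags the path inward, shortening every segment by roughly one radius. A
single unrestricted step (the simplest conceivable correction) leaves
staircase artefacts worth several percent of length; the iterated radial
ascent brings a 0.5 mm-voxel cylinder to within 0.5% of its true length
with sub-voxel axis deviation. Path endpoints stay pinned to the snapped
seeds.

Downstream, the path is resampled at 1 mm and smoothed with a centred
moving average (window 5, endpoints pinned, window shrinking symmetrically
near the ends so segment cut points cannot drift). Neither parameter is
dictated by the protocol being modelled; both are configuration knobs, and
the defaults are the coarsest values at which phantom recovery meets the
package's own tolerances (length within 1%, tortuosity within 0.01 at
0.5 mm voxels).

## Registration

All of a patient's acquisitions are brought into the pre-operative
straight-knee frame by rigid registration on the femur, which is rigid
across limb postures. The core is classical ICP: nearest-neighbour
correspondence (uniform-grid locator, exact), closed-form SVD/Kabsch update,
monotone non-increasing RMS (non-improving steps rejected), stopping when
the RMS improvement falls below 1e-4 mm.

Two robustness layers sit around the core:

* **Initialization.** Centroid + principal axes leaves two ambiguities on a
  near-cylindrical bone: the four proper sign flips and the azimuth about
  the long axis. All four flips crossed with a 15° azimuth sweep are scored
  by initial RMS on a subsample; a diverse subset (pairwise at least 15°
  apart) is probed with short ICP runs and the best basin is refined fully.
* **Point-to-plane polish.** Point-to-point ICP between two different
  discretizations of the same surface has a pose bias at the vertex-spacing
  scale. A final refinement matches each point to the foot of the
  perpendicular onto its neighbour's local tangent plane (normals from
  local PCA), which removes most of that bias.

On phantoms, identical sampling recovers the true transform to numerical
precision; independently meshed bones with 0.2 mm vertex noise are
recovered to better than 1° and 0.5 mm. Since all metrics are rigid
invariants, morphometry is identical before and after registration — the
step exists to put geometries in a common frame, and the tests assert
exactly that.

## The limb phantom

The phantom generator stands in for the study cohort, so its defaults are
chosen once, as anatomy, and not revisited:

* vessel axis: 510 mm along the limb with gentle sinusoidal excursions
  (AP amplitude 3 mm / wavelength 210 mm, lateral 7 mm / 150 mm, per-patient
  jitter ±30% on amplitudes, ±15% on wavelengths, random phases). These
  give straight-knee tortuosities of a few times $10^{-2}$, the clinical
  scale, with the lateral excursion dominating the straight posture —
  consistent with reported straight-knee decompositions where the lateral
  component exceeds the frontal one;
* adductor hiatus at 290 mm, knee hinge at 360 mm, so the SFA is ~290 mm
  and the PA ~220 mm, the clinical medians;
* lumen: SFA radius 4 mm tapering to 3.5 mm; pre-operative phantoms carry a
  fusiform aneurysm sac (Gaussian bulge, amplitude 3.5 mm, σ = 8 mm,
  centred 320 mm) in the PA; follow-up phantoms replace the sac with a
  3.25 mm stented lumen;
* bones: capped cylinders (femur proximal, tibia distal to the hinge) with
  three tall asymmetric surface bosses that make the azimuth observable to
  ICP. Ring vertices are golden-angle staggered with deterministic
  per-vertex angular jitter — a regular ring lattice would hand ICP a comb
  of spurious minima at multiples of the angular step, an artefact of
  vertex sampling, not of the surface;
* bending: geometry distal to the hinge rotates rigidly about the
  medio-lateral hinge axis by 180° − knee angle (90° by default); the
  vessel axis within ±20 mm of the hinge is replaced by a cubic Hermite
  blend matching position and tangent at both ends, with tangent magnitudes
  scaled to the blend chord. Arteries bend smoothly, not with a crease, and
  the blend keeps the curvature radius comfortably above the lumen radius
  so the re-swept tube cannot self-intersect (the sweep rejects any profile
  whose radius exceeds half the local curvature radius);
* acquisition frames: the bent acquisition is additionally moved by a
  random rigid transform (≤15°, ≤20 mm), emulating repositioning between
  scans; this is the transform registration must recover.

Tube surfaces are swept with rotation-minimizing frames (64 vertices per
ring, keeping the polygon-vs-circle area deficit below 0.2%). Voxelization
marks a voxel foreground iff its centre lies inside the closed surface
(even-odd ray parity, compiled); voxel centres carry unequal sub-voxel
offsets per axis because a grid aligned or symmetric with the object's
symmetry planes biases foreground counts by several percent — real scanner
grids are arbitrary with respect to anatomy. Default spacing is 0.5 mm
isotropic, the typical lower-limb CTA class. The hinge position relative to
the hiatus is a parameter (`hinge_z`), since no protocol fixes where a
padded support sits relative to that landmark.

What the phantoms deliberately do not model: soft tissue and muscle, lumen
contrast and noise (masks are clean), bifurcations (a single conduit),
wall thickness, stent struts, and non-rigid arterial wall mechanics. A
passing phantom suite therefore validates the *measurement chain*, not the
segmentation step that precedes it in clinical use.

## The synthetic cohort sampler

The statistics layer is exercised on cohorts drawn around published
summary cells (median and IQR per metric × segment × posture × timepoint,
from a nine-patient popliteal-aneurysm cohort; shipped as a CSV fixture).
Each cell is a log-normal — all quantities are positive and only
median/IQR are reported — with `sdlog` solved in closed form from
$\mathrm{IQR} = m\,(e^{z\sigma} - e^{-z\sigma})$, $z = \Phi^{-1}(0.75)$.
Within a patient, the four posture × timepoint variants of a metric share
an equicorrelated Gaussian copula (ρ = 0.8), giving the strong
within-patient pairing that paired testing needs; patients are i.i.d. from
a single seeded stream. (An earlier design derived one RNG stream per
patient from arithmetically related seeds; the first draws of such streams
are measurably correlated under the Mersenne–Twister, biasing cell medians
— a reminder that per-unit `set.seed` is not a substitute for proper
stream derivation.)

By default the sampler is *sample-calibrated*: each cell's draws are
rescaled rank-preservingly in log space so the sample median and IQR equal
the targets exactly, at any cohort size — the median/IQR analogue of
drawing multivariate normals with exact empirical moments. This makes
"tuned to the published cells" literally true of every generated cohort
and removes the $O(n^{-1/2})$ sample-median wobble (≈1.3% at n = 2000 for
the most dispersed tortuosity cells) that would otherwise dominate
convergence checks. `calibrate = "population"` restores plain i.i.d.
draws.

## Statistics

Summaries are median (IQR) with the linear-interpolation quantile
convention (R type 7) — at n = 9 the IQR depends on this choice, so it is
fixed and documented. Percentage variation between postures is
$(m_\text{straight} - m_\text{bent})/m_\text{straight} \times 100$, signed;
the reporting layer renders magnitude plus a direction word. Pre-vs-post
comparisons reuse the formula with the pre-operative median as baseline.

Paired comparisons test the differences $d_i = a_i - b_i$ for normality
and gate on the result: Lilliefors-corrected Kolmogorov–Smirnov by default
(a plain KS test against a fully specified normal is almost never the
applicable variant when mean and SD come from the data; the plain variant
on standardized differences remains available), then a paired t-test if
normality is not rejected at 0.05, otherwise the two-sided Wilcoxon
signed-rank test (zeros dropped, midranks for ties, exact p for n ≤ 25
without ties, normal approximation with continuity correction above). All
differences zero returns p = 1 with a warning. No multiplicity correction
is applied anywhere, matching the analysis style the package reproduces.
Monte-Carlo calibration (1000 null cohorts at n = 9 and n = 50) keeps the
empirical type-I error within [0.03, 0.07] and selects the t-branch on
≥ 90% of Gaussian cohorts.

A follow-up-time regression (`fu_regression`) checks that measured
variations are not driven by how long after treatment the follow-up scan
was taken: ordinary least squares of variation on follow-up months, with
$R^2$ and the two-sided slope p-value.

## Problem sizes and runtimes

The shipped tests run the full chain at the study's native scale where
that is cheap (ICP, statistics, decomposition) and at reduced cohort size
where it is not: the end-to-end phantom block measures 2–3 patients (each
one straight + bent acquisition at 0.5 mm voxels, ~1.3–5 million voxels
per mask), which exercises every stage identically to a larger cohort.
Statistical calibration uses 1000 Monte-Carlo cohorts; sampler convergence
uses 2000 synthetic patients. A full suite runs in a few minutes on one
core.

## Known limitations

* The extraction guarantees hold for tube-like, non-branching lumens; at
  branch points the single-path geodesic would shortcut.
* Diameter assumes circular sections exactly; a strongly elliptical lumen
  (e.g. under extrinsic compression) is summarized by its area-equivalent
  circle, not fitted as an ellipse.
* Point-to-plane ICP refinement assumes locally smooth surfaces; on very
  coarse meshes (vertex spacing ≫ feature size) residual pose bias of a
  fraction of a degree remains.
* The printed clinical medians/IQRs ship as fixtures; the raw per-patient
  values behind them are not redistributable, so the statistics layer can
  reproduce the published percentage variations from the medians but not
  the published p-values, which depend on the raw pairs.
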