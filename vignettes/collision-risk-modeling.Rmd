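---
title: "Modeling intracardiac collision risk of leadless pacemakers on the RV septum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intracardiac collision risk of leadless pacemakers on the RV septum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpmcollide)
```

## The problem

Leadless pacemakers (L-PMs) are rigid capsules implanted in the right
ventricle.  Placing one on the RV septum — the target for leadless left
bundle branch area pacing (LBBAP) — puts it amid moving intracardiac
structures: the RV free wall, the papillary muscles (PMs) and moderator
band, and the tricuspid valve (TV) apparatus.  Mechanical contact with any
of these is a plausible mechanism for ventricular ectopy and for
tricuspid-regurgitation worsening, so a natural screening question is: *for
a capsule of given length and diameter implanted perpendicular to the
septum at a given node, does its swept position over the cardiac cycle
intersect any structure?*

`lpmcollide` answers this question for every septal node of a dynamic RV
anatomy, for any device design, and aggregates the answers into regional
risk statistics on the standard AHA septal segments (2, 3, 8, 9, 14), the
LBBAP target regions (proximal left bundle branch LBB and the anterior,
posterior and septal fascicles LAF/LPF/LSF), and the 20-mm band below the
TV annulus that clinical studies associate with valve dysfunction.

## Collision model

A device is a flat-capped right circular cylinder: base point on the
endocardial septal surface, axis along the inward septal normal, length
$L$ and radius $r$ (no fixation helix, no insertion depth).  Tissues are
rigid; *collision* means solid–solid overlap of the cylinder with a closed
structure mesh, with **no minimum-overlap threshold** — a site is positive
for a category if it collides in at least one of the cardiac phases, and
positive for *combined* risk if any category is positive.

The geometric predicate is exact rather than sampled.  For each triangle
the axial coordinate $s = (x - b) \cdot \hat a$ is clipped to the end-cap
slab $0 \le s \le L$; the triangle then meets the cylinder solid iff the
clipped polygon's minimum radial distance to the axis line is below $r$.
This single test covers lateral-surface and end-cap contact.  Two
containment tests complete the predicate: the axis midpoint against the
mesh solid (cylinder swallowed by a structure) and mesh vertices against
the cylinder (thin structure fully pierced; only needed for excluded
faces, because the exact face test already covers every vertex of a
non-excluded face).  Point containment uses the ray-parity rule with
deterministic direction retries on degenerate hits.  A face-based AABB
tree accelerates all queries.  All distance comparisons use a fixed
tolerance of $10^{-6}$ mm; exact surface grazing (zero-measure contact)
counts as no overlap, except that a face lying exactly in an end-cap plane
with the axis crossing it is reported as contact — the boundary convention
is irrelevant at the resolutions used, and every randomized verification
scene is filtered to verdicts robust to a ±15 % size perturbation.

Attachment-site self-intersection is prevented by excluding RV-wall faces
whose centroid lies within 10 mm (Euclidean, configurable) of the device
base from the *surface* test only; containment tests always use the full
solid, so a device can never tunnel through a distant wall unnoticed.  The
septum itself is never a collision target.

An independent Monte-Carlo oracle (`overlap_oracle`) samples points
uniformly in each solid and tests them against the other; the test suite
requires zero disagreements with the exact predicate over 1000 randomized
robust scenes.

## Synthetic dynamic anatomy

Real 4D CT-derived meshes can be supplied through `read_scene_sequence`
(VTK legacy, PLY, OBJ; constant per-category topology across frames is
enforced).  Because suitable public data with labeled papillary muscles is
not available, the package ships a parametric generator that emulates the
relevant statistical structure of a dilated heart-failure RV:

* **Cavity**: a truncated half-ellipsoid, apex at the origin, basal
  (annulus) plane at the long-axis length (default 95 mm), with the medial
  sector (half-angle 60°) flattened into a planar septal chord.  The basal
  radius is calibrated so the discrete end-diastolic volume matches
  `edv_target` (default 283 mL — the dilated-RV cohort mean) to well under
  2 %.
* **Free wall**: the non-septal endocardium offset outward by 3.5 mm
  (literature RV wall thickness) into a closed shell.
* **TV apparatus**: a 2-mm-thick annulus-plane slab (ring radius 18 mm)
  plus a closed loft ("cone") from the chordae attachment points to the
  annulus ring, enclosing leaflets and chordae.  The annulus centre sits
  8 mm off the septum and 18 mm toward the inferior wall: in the real RV
  the basal *anteroseptal* region faces the valve-free outflow tract while
  the TV septal leaflet runs along the basal *inferoseptal* border.  An
  idealized centred ring would wrongly spread valve risk into the
  anteroseptal segment.
* **Papillary muscles and moderator band** (one collision category):
  three closed tapered cones whose tips — the basal-most points — are the
  chordae attachment points feeding the TV cone.  RV papillary muscles
  arise in the apical half (the anterior PM springs from the moderator
  band near the apex), so the attachments default to normalized heights
  0.40/0.45/0.55 with the moderator band crossing the apical third.
* **Motion**: an analytic advected field — radial contraction toward the
  long axis plus half-amplitude longitudinal shortening — scaled by
  $w(t) = (1 - \cos 2\pi t)/2$ over 10 phases.  The amplitude is found by
  scalar root-finding so the minimum cavity volume equals
  $\mathrm{EDV}(1 - \mathrm{EF}/100)$; since the field is affine per
  frame, the calibration is exact at the mid-cycle frame.  All structures
  and landmarks are advected by the same field, so topology never changes.
* **Cohort**: log-normal multiplicative jitter on the size parameters
  (EDV fractional SD 38/283, matching the reference cohort), additive
  normal jitter on EF (SD 7 %, clamped to [3, 60] %), PM dimensions scaled
  with the cube root of the volume factor.  A single seeded generator
  drives everything; the same seed reproduces the cohort bitwise.

What the generator does *not* emulate: trabeculation, regional wall-motion
abnormality, a true outflow tract, leaflet geometry inside the TV cone,
and image-derived non-affine deformation.  Passing tests on this cohort
therefore demonstrate the correctness and the qualitative behaviour of the
*method* (risk increasing with device length, valve risk confined to the
annulus band, apical wall crowding), not patient-level accuracy on real
anatomy.

## Coordinates and regions

Septal nodes are parameterized by $\rho$ (normalized projection on the
apex → annulus-centre axis, 0 apex / 1 base) and $\varphi$ (normalized
signed angle between the anterior and posterior RV attachment lines).
Because the annulus centre is deliberately off-axis, the $\rho$ axis is
slightly tilted and basal-plane nodes spread a little below 1; both
coordinates are clamped to $[0,1]$ and are exactly invariant under rigid
transforms.  AHA labels follow thirds in $\rho$ with the
anterior/inferior split at $\varphi = 0.5$; the apical third is a single
segment (14).  LBBAP regions are the convex hulls of the fascicle seed
paths in the flattened $(\rho, \varphi)$ chart — convexity is only well
defined there — dilated by a 5-mm-equivalent margin, with ties resolved
toward the nearest path centroid and degenerate (collinear) hulls falling
back to a buffered corridor.  Cross-patient maps use nearest-node binning
on a 50×50 $(\rho, \varphi)$ grid (configurable; empty cells are flagged
missing rather than interpolated).

## Statistics

Regional prevalence is computed per patient (`100 × positive sites /
region sites`) and summarized as mean ± SD across patients, with the
*population* (divide-by-$n$) SD — that convention reproduces the reference
cohort's printed summary row (283 ± 38 mL) exactly, where the sample SD
does not.  The whole-septum value is consequently the site-weighted
average of the AHA regional values, an identity the tests assert.
Collision-free fractions of the LBBAP regions pool sites across patients
instead, because they describe the fraction of regional *area* available.
Device-length trends are ordinary least squares of mean risk on length
(slope reported per 5 mm, with Pearson r); device pairs are compared with
paired t tests, Bonferroni-corrected by the declared family size.
Mixed-effects models and ANOVA are deliberately not implemented — the
site-level CSV outputs are structured so any statistics environment can
fit them.

## Device designs

The contemporary catalogue is Micra TPS (25.9 mm), Aveir AR (32.2 mm) and
Aveir VR (38 mm).  Only lengths and coarsely rounded volumes are public,
so the diameters are configurable constants with manufacturer-nominal
defaults (6.7 / 6.5 / 6.5 mm), and every result table records the values
used.  Design sweeps vary length over 15–45 mm in 5-mm steps while holding
the base device's volume fixed (battery-capacity proxy), the diameter
following $d = 2\sqrt{V / (\pi L)}$.

## Numerical choices and problem sizes

The default mesh resolution (96 apicobasal × 60 circumferential) yields
about 2000 septal implant sites per patient and keeps the full
10-patient, 18-device analysis (catalogue + three 5-length sweeps) within
a few minutes on one core; the examples and unit tests use coarser
24 × 18 meshes where only correctness, not map smoothness, matters.
Refining the mesh changes regional prevalences by well under the
interpatient spread.  Orientation sensitivity re-runs the assessment with
the axis tilted by an angle uniform in [0°, 5°] about a uniform azimuth,
reporting per-site positive fractions — mirroring the perpendicularity
assumption's known optimism.

## Known limitations

Rigid tissues overstate the clinical meaning of small overlaps; discrete
per-frame testing (10 phases) can miss inter-frame grazing contact;
conduction targets are geometric corridors, not electrophysiology; the
idealized anatomy cannot rank real patients.  The intended use is method
development, device-design screening, and as a harness into which real
labeled mesh sequences can be dropped via the standard formats.
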