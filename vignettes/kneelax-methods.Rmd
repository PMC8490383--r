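---
title: "Measuring knee laxity from stress MRI: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring knee laxity from stress MRI: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneelax)
```

## The measurement problem

The posterior cruciate ligament (PCL) restrains posterior tibial
translation (PTT). A stress-MRI posterior drawer test images the knee twice
per ligament condition — unloaded (δ0) and under a standardized 147 N
posterior load (δ1) — and quantifies how far the tibia moves relative to
the femur. `kneelax` turns segmented bone masks plus six registered
landmarks into those laxity numbers. The package deliberately does *not*
segment, register images, or simulate MR contrast: masks and landmark
coordinates are its inputs.

## Grid geometry and coordinate conventions

A measurement cell lives on an anisotropic stack: 0.6 × 0.6 mm in-plane and
3.0 mm slices separated by a 0.3 mm gap, so the effective spacing along the
slice axis is 3.3 mm. Voxel indices are 0-based; world coordinates are
millimetres with the origin at the corner of voxel (0, 0, 0); index i maps
to i × spacing. These choices are package conventions — segmentation tools
disagree on them, so they are fixed and versioned in the landmark schema.

Array axes carry the anatomy: x mediolateral, y anteroposterior,
z craniocaudal, with the coarse (slice) axis on z. The *anatomical frame*
adds signs: +x lateral, +y posterior, +z cranial. Left knees are mirrored
about the grid extent in x so that +x is lateral on both sides; the mirror
is an involution and applied after all intra-volume geometry, so it cannot
bias distances. The sign conventions themselves (which direction counts as
positive) are package decisions; published laxity tables report signed
changes without defining them, and any fixed choice yields the same
magnitudes.

A note on an ambiguity this field carries: tabulated laxity results
sometimes label x as anteroposterior and y as mediolateral, the transpose
of the convention above. `kneelax` follows the mediolateral-x /
anteroposterior-y reading consistently; posterior translation therefore
always appears in y components (`y_ASI`, `y_FT`).

## 3D vector measures

Two point pairs summarise femorotibial position:

* **FT → TT** (`vector_FT`): manually registered landmarks, converted to mm
  and to the anatomical frame; purely landmark-driven.
* **fASI → tASI** (`vector_ASI`): computed fixpoints. Each bone's central
  axis is the line through its proximal and distal shaft-centre landmarks,
  oriented toward the joint (distally for the femur, proximally for the
  tibia). The axis–surface intersection is the point where that line,
  marched from inside the bone toward the joint, last leaves the bone mask.

Components are head minus tail with the femoral point as tail, so a
posteriorly displaced tibia increases +y. Magnitudes are Euclidean norms;
the suite checks `magnitude² = Σ components²` at 1e-6 relative tolerance on
every computed vector.

### Numerical choices in the intersection

* Marching step = ¼ of the smallest voxel spacing (0.15 mm on the study
  grid). This balances cost against the strong 3.3 mm slice anisotropy; the
  sub-voxel exit point interpolates linearly between the last inside and
  first outside sample, i.e. their midpoint for a binary mask.
* Membership is nearest-voxel lookup; points outside the grid are outside
  the mask.
* If the line crosses the mask in several disjoint runs (possible with
  osteophytes or segmentation debris), the joint-side crossing is used and
  a warning emitted.
* Masks are hole-filled per slice before intersection
  (`EBImage::fillHull`, with a scanline fallback) so hollow cortical shells
  behave like solid bone. The joint-side-crossing rule would return the
  outer cortical exit even unfilled; filling keeps the inside/outside test
  well defined everywhere.
* Degenerate inputs error early: coincident shaft centres (no axis), an
  axis that never enters the mask, or a mask touching the marching bound.

Tests compare the implementation against an independent dense-marching
comparator (fixed 0.02 mm step, written separately in the test helpers) on
20 random ellipsoidal solids; agreement is required within one coarse step.

## 2D reference measures

The classical caliper measures are automated on the central sagittal slice
of each femorotibial compartment:

* The **plateau region** of the tibia is everything within 15 mm of its
  most cranial extent — deep enough to span the plateau slab on a 3.3 mm
  stack, shallow enough to exclude the shaft.
* The compartment's mediolateral span is the plateau footprint split at its
  midpoint; the **central slice** is the lower-median column of the
  compartment's footprint (fixed tie-break), chosen once on the unloaded
  intact cell of each specimen and reused for its other five cells, exactly
  as serial manual measurements keep their slices fixed.
* **mPTT/lPTT**: most posterior plateau point minus most posterior femoral
  condyle point along y (condyle = femur within 20 mm of its most caudal
  extent); posterior tibial displacement is positive.
* **AD/PD**: horn base minus plateau border along y. "Horizontal" is read
  as the anteroposterior axis of the sagittal slice, matching the loading
  direction. The horn **base** is the centroid of the horn's most caudal
  (plateau-contact) pixel row — a deterministic stand-in for the reader's
  caliper placement, since no anatomical definition of the base exists.
* **API**: inner edge of the posterior horn minus inner edge of the
  anterior horn. Horns are the first and last runs of the meniscus
  footprint along y.

All 2D measures are invariant under whole-image translation (tested), and
`lPTT − mPTT` responds with the correct sign to internal tibial rotation
about a medial pivot.

## The synthetic phantom

No public dataset pairs stress-MRI masks with known kinematics, so the
package generates its own. Bones are stylized solids — shaft cylinders,
condylar spheroids, a trochlear ridge (defining FT), a plateau slab with a
tuberosity boss (defining TT), and two annular meniscal wedges — because
every measure in the package depends only on boundaries, axes, and
landmarks, not on anatomical realism. Each cell applies a rigid transform
to the tibia + menisci: translation plus internal rotation about a pivot in
the medial plateau compartment plus a small flexion perturbation. Landmarks
are the analytic positions plus Gaussian registration jitter (default
SD 0.5 mm, the scale of observed intra-reader deviations for well-defined
landmarks).

Default study conditions: 11 specimens (6 left, 5 right), three conditions
× two configurations. Loaded-configuration responses are drawn per
condition with medial posterior translation 2.4 ± 1.2 / 3.7 ± 2.1 /
11.8 ± 4.9 mm (intact/partial/complete) and internal rotation
7.5° / 7.2° / 1.6° (SD 2°) — chosen so the compartmental translations and
their lateral-over-medial excess match the magnitudes a posterior drawer
study reports, including the near-equalisation of the two compartments in
complete deficiency. Unloaded intact cells are the exact identity (they are
the baseline); unloaded partial/complete cells receive residual offsets
(SD 2 mm) emulating imperfect repositioning between sessions. Specimen
variability (joint position, plateau width) is Gaussian truncated at ±2 SD,
because the acquisition adapts its field of view to the anatomy — the joint
never leaves the grid.

What the phantom does *not* emulate: MR intensity and artefacts,
segmentation error beyond geometric voxelization, soft-tissue deformation
(menisci move rigidly with the tibia), and inter-reader variability.
Passing recovery tests therefore demonstrates the correctness of the
measurement geometry and bookkeeping under realistic sampling and jitter —
not robustness to segmentation quality.

Determinism: a `phantom_spec` seed fixes the dataset bit-for-bit, each
specimen derives from `seed + 1000·index`, and restricting generation to a
subset of cells does not change the draws of the rest.

## Statistics

* **Repeated-measures ANOVA**: the six condition × configuration cells are
  one within-specimen factor, matching designs that report a single p per
  measure. The F statistic is computed from the classical sums-of-squares
  decomposition (treatment, subject, interaction-as-error); tests verify
  exact agreement with `stats::aov` and, in the two-cell reduction, with
  the squared paired t statistic.
* **Post-hoc family**: comparisons against the unloaded intact baseline
  (m = 5) by default — the contrasts a laxity table actually interprets —
  with all 15 pairs as an option; Bonferroni adjustment
  `min(1, m·p)`. Significance is stratified at p ≤ 0.01 (`**`) and
  p ≤ 0.001 (`***`).
* **Sphericity**: no correction by default (mirroring common practice in
  this literature); a Greenhouse–Geisser option is provided.
* **Normality** is assumed, not tested.
* **Power**: `sample_size_paired()` returns the smallest n whose two-tailed
  paired t test reaches the target power under a noncentral-t alternative
  with noncentrality d·√n. At d = 1.4, power 0.8, α = 0.05 the standard
  calculation gives n = 7. Study-planning reports built on the same inputs
  sometimes state ten; a web calculator of unknown internals cannot be
  reverse-engineered, so the package reports the standard result and leaves
  the discrepancy documented here rather than forcing agreement.

Monte-Carlo validation (in the suite and `scripts/acceptance.R`): with zero
condition effect, 11 specimens and 2000 replicates, the rejection rate at
p ≤ 0.01 must lie in [0.005, 0.017].

## Problem sizes and known limitations

The suite validates recovery on 20 jittered specimens (two cells each),
runs the full 11-specimen study for end-to-end determinism, and uses
reduced grids for the geometry oracles; these sizes make the whole suite
run in a few minutes while keeping every statistical check at its stated
tolerance.

Limitations worth keeping in mind:

* The recovery error of `y_ASI` (≈1 mm mean absolute at 0.5 mm jitter) is
  dominated by extrapolating the tibial axis from shaft landmarks to the
  plateau — the same lever-arm amplification a human reader's registration
  error would suffer.
* Compartment selection assumes a single connected plateau footprint;
  grossly fragmented segmentations will mislead the midline split.
* The intact-versus-partial separation under the default conditions is
  small relative to its variability, so single simulated studies can fail
  to order those two conditions — consistent with the clinical difficulty
  of distinguishing partial deficiency.
* 2D measures quantise at one in-plane pixel (0.6 mm); slice-axis (z)
  quantities quantise at 3.3 mm and are reported but should be interpreted
  accordingly.
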