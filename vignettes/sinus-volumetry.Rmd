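---
title: "Deterministic sinus segmentation and interval volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic sinus segmentation and interval volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinusvol)
```

## The problem

The maxillary sinus is an air-filled cavity in the maxilla. On cone-beam
computed tomography (CBCT) it appears radiolucent (dark) against the
radiopaque (bright) bone that bounds it. Implant surgery in this region
— zygomatic or pterygoid implants placed through or near the sinus — can
change the cavity's shape and volume, so surgeons want a reproducible,
operator-light way to measure sinus volume before and after an
intervention. Deep-learning segmenters do this well but need large
annotated training sets; `sinusvol` instead implements a deterministic,
rule-based pipeline whose every step is inspectable, and which therefore
needs no training data at all.

## The segmentation model

The input is an ordered stack of grayscale slices, each an integer
matrix with values 0–255, plus a single *seed voxel* the operator
asserts to lie inside the sinus, and a global *binarization threshold*
`k`.

1. **Binarization.** Every slice is thresholded with `k`. The default
   polarity marks intensities `>= k` as foreground; because an air
   cavity is dark, the practically useful polarity for sinus work is
   `foreground_lt` (foreground where intensity `< k`). The pipeline
   refuses to run when the seed voxel is background, which catches a
   wrong threshold or polarity immediately.
2. **Surface labelling.** Within each slice, foreground pixels are
   partitioned into *surfaces*: maximal sets connected through chains of
   pixels at pairwise L1 distance 1 — i.e. 4-connected components.
   Labels are numbered by each component's first pixel in row-major
   order, so labelling is fully deterministic.
3. **Seed propagation.** In the seed's slice only the seed's surface is
   kept. The stack is then swept outward; a surface in an adjacent plane
   joins the detection iff one of its pixels sits at in-plane L1
   distance ≤ 1 (same position or a 4-neighbour offset) from an
   already-retained pixel.
4. **Septum removal** (optional, `layers = l > 0`). Partial-volume
   effects can make the sinus appear connected to a neighbouring cavity
   through a thin "invisible septum". For each plane the pipeline
   erodes the binarized slice `l` times with the plus-shaped
   structuring element (a pixel survives iff it and its four orthogonal
   neighbours are foreground), keeps only the eroded components
   contiguous with the reference pixels (the sinus already identified
   in the adjacent plane, or the seed), and then runs **exactly `l`**
   reconstruction passes in which every boundary pixel re-adds its
   orthogonal neighbours that were foreground in the original slice.
   A channel of width ≤ `l` vanishes during erosion and — because
   reconstruction is bounded to `l` passes — can regrow by at most an
   `l`-pixel stub, so the far cavity is never re-entered.
5. **Forward/reverse refinement.** Newly retained pixels can make
   further surfaces reachable (think of a U-shaped cavity entered at
   the top of one arm). Full forward and reverse passes are repeated
   until a pass adds no pixel. The result is monotone, bounded by the
   binarized foreground, idempotent, and — for a stack whose foreground
   is one connected solid under the contiguity rule — provably equal to
   the seed's 3D connected component (the test suite checks this
   against an independent 3D flood fill).

## Interval volumetry

Assuming detection errors live only on the boundary, the package brackets
the true volume instead of reporting a single count:

- the **lower bound** keeps a pixel iff itself and its four orthogonal
  neighbours are foreground (the boundary layer removed);
- the **upper bound** keeps a pixel iff its five-term neighbourhood sum
  is ≥ 1 (one layer added);
- each voxel contributes a cube of side `L`, so with counts
  `n_lower ≤ n ≤ n_upper` the report is the midpoint
  `V = (V_upper + V_lower) / 2` with error `±(V_upper − V_lower) / 2`.

Both rules are applied per slice, exactly as defined on a single
matrix; there is no through-plane erosion or dilation. Out-of-bounds
neighbours count as background, so pixels on the image edge never enter
the lower bound. An anisotropic mode (`spacing = c(dz, dy, dx)`)
replaces `L³` by `dz·dy·dx` for non-cubic voxels; the default stays the
cubic model. The volume unit is a label (`"mm^3"` by default) — the
numbers are whatever `L`'s cube implies.

For paired scans the relative change is `ΔV_rel = (V_pre − V_post) /
V_pre`, rendered as a percentage rounded half-up to one decimal.
`cohort_summary()` adds the across-sample mean, the sample standard
deviation (n − 1 denominator), and the two-sided Student-t interval
`mean ± t_{1−α/2, n−1}·sd/√n`.

```{r cohort}
cohort <- read.csv(pilot_cohort_path())
cs <- cohort_summary(cohort)
cs
glance(cs)
```

## Agreement metrics

`cohens_kappa()` computes voxelwise chance-corrected agreement over the
full bounding grid — background concordance counts, matching the
voxel-level definition of observed agreement as the fraction of voxels
with the same label. `dice_coefficient()` is `2|A∩B|/(|A|+|B|)` over
foreground sets, and `consensus_union()` builds the union reference
standard from two manual annotations. Degenerate inputs are reported as
undefined (`NA`) rather than silently coerced: kappa when both raters
are constant and identical (`pe = 1`), Dice when both masks are empty.

## The synthetic phantom

Real CBCT data cannot ship with a package, so validation runs on
seeded synthetic phantoms: dark ellipsoidal cavities (intensity 30) in
a bright matrix (intensity 200), optionally joined by thin axis-aligned
channels, with optional rounded Gaussian noise clamped to [0, 255].
Ellipsoids were chosen because their analytic volumes (`4/3·π·a·b·c`)
and exact lattice counts give independent oracles. Defaults encode a
comfortably separated two-class intensity model; with `noise_sd = 15`
the class gap is about 11 standard deviations at the midpoint threshold,
which emulates a clean clinical acquisition rather than a noisy or
artifact-ridden one.

What the phantoms deliberately do **not** model: anatomical sinus
shapes, partial-volume gradients at real bone–air interfaces,
beam-hardening, or the high-contrast implant artifacts that forced
occasional manual correction in clinical use. Passing phantom tests
therefore demonstrates algorithmic correctness (the implementation
computes the procedure it claims), not clinical segmentation accuracy.

`generate_pre_post_pair()` emulates the paired surgical design by
scaling the primary cavity's semi-axes by a shrink factor `f`: the
continuous truth is `ΔV_rel = 1 − f³` for isotropic scaling, and the
voxelized truth comes from exact lattice counts.

## Numerical and design choices

- **Binarization polarity.** The threshold rule is printed with `≥ k`;
  because the sinus itself is dark, both polarities are exposed and the
  seed-foreground check guards the choice.
- **Erosion requires the centre pixel.** The erosion rule is
  implemented as standard plus-shaped erosion (centre and all four
  neighbours foreground); conditioning on the neighbour sum alone would
  let background holes fill during "removal", which contradicts the
  operation's purpose.
- **Reconstruction runs exactly `l` passes** and is bounded by the
  original slice. Unbounded geodesic reconstruction would crawl back
  through the severed channel and defeat septum removal. A consequence
  worth knowing: pixels at in-mask L1 distance > `l` from the eroded
  core — the diamond-corner pixels of squarish blobs — are not
  recovered. The attrition is confined to the boundary ring, i.e.
  exactly the voxel class the volume interval is built to absorb, and
  the test suite pins it against a brute-force constrained-dilation
  oracle. Shapes that are diamond-convex (L1 balls) are recovered
  exactly.
- **Fallback when erosion empties a slice.** Near the top and bottom of
  a rounded cavity the in-plane cross-section is thinner than `l`;
  eroding it away would truncate the detection. Such slices fall back
  to plain (no-septum-removal) retention and are recorded in the
  result's `fallback_slices`.
- **Contiguity window.** Adjacency evaluation between planes is
  restricted to a window around the reference pixels (half-width
  `2l + 1` by default). Since the contiguity relation itself has radius
  1, the window is a search-bounding device and does not change the
  result.
- **Sweep scheduling.** Refinement alternates full forward and reverse
  passes until a pass adds nothing, with a guard of `n_slices` pass
  pairs (a monotone bounded process; the guard only trips on a logic
  error).
- **Determinism.** Labelling order, sweep order and tie handling are
  all fixed; the only stochastic element anywhere is phantom noise,
  which is seeded and recorded.
- **Rounding.** Printed percentages use round-half-up to one decimal,
  the convention of the clinical table the cohort statistics reproduce;
  `round()`'s banker's rounding would differ on exact .05 boundaries.

## Problem sizes used in validation

The shipped tests and the acceptance script validate on: random masks
up to 32×32 (1000 seeded trials per operation against brute-force
oracles), voxelized spheres of radius 8–12 in stacks up to 31³,
pre/post pairs with shrink factors 0.8–1.0, the canonical two-blob
septum fixture, and the six-sample pilot cohort. These sizes keep the
whole validation suite runnable on a laptop in well under a minute per
stage while leaving the sphere discretization error (the quantity the
interval must absorb) clearly visible.

## Known limitations

- `k` is a single global threshold; no adaptive or gradient-based
  thresholding. Choosing `k` per scan remains an operator decision.
- Septum removal is strictly per-plane (no 3D structuring elements),
  mirroring the per-slice definition of the procedure.
- No registration between pre- and post-operative scans: volumes are
  compared as scalars, not voxelwise.
- DICOM series input is not supported in this build; stacks arrive as
  8-bit image directories or NIfTI volumes (`rescale_to_8bit()` handles
  windowing wider dynamic ranges).
- Boundary-pixel attrition of the reconstruction step, described above.
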