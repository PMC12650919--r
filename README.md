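# sinusvol

Deterministic segmentation and interval volumetry of the maxillary
sinus from tomographic slice stacks.

## What it is for

Zygomatic and pterygoid implant surgery can reshape the maxillary
sinus, and surgeons planning or following up such interventions need
reproducible volume measurements from CBCT scans. `sinusvol` implements
a rule-based, training-free pipeline for that job, aimed at clinical
researchers who want every segmentation step to be inspectable rather
than learned: no annotated training cohort, no GPU, and bit-for-bit
reproducible runs.

## The method in brief

Given a stack of 0–255 grayscale slices `I`, a seed voxel inside the
sinus, and a global threshold `k`:

1. **Binarize**: `M_ij = 1` iff `I_ij ≥ k` (or `< k` for dark, air-filled
   targets — the sinus case).
2. **Label surfaces**: 4-connected components per slice (pixels chained
   at L1 distance 1).
3. **Propagate the seed**: keep the seed's surface, then add any surface
   in an adjacent plane containing a pixel at in-plane L1 distance ≤ 1
   from a retained pixel; sweep outward, then iterate full
   forward/reverse passes to a fixpoint.
4. **Sever invisible septa** (optional, depth `l`): erode `l` plus-shaped
   layers, keep the components contiguous with the sinus in the
   neighbouring plane, then run exactly `l` bounded reconstruction
   passes — thin channels to neighbouring cavities vanish and cannot
   regrow beyond an `l`-pixel stub.
5. **Volume with an error bar**: per slice, a lower bound removes the
   boundary layer (`M_ij + 4-neighbour sum = 5`) and an upper bound adds
   one (`sum ≥ 1`); with cubic voxels of side `L`,

   V = (V_upper + V_lower) / 2, err = (V_upper − V_lower) / 2.

For paired scans, `ΔV_rel = (V_pre − V_post) / V_pre`, with cohort
mean, SD and a Student-t 95% CI. Voxel-level agreement between two
segmentations is scored with Cohen's kappa and the Dice coefficient.

## Worked example

Segment a synthetic phantom (a dark spherical cavity of radius 10
voxels in bright matrix) and measure it with 0.3 mm voxels:

```r
library(sinusvol)

ph <- generate_phantom(phantom_spec(
  shape    = c(27, 27, 27),
  cavities = list(list(center = c(14, 14, 14), semi_axes = c(10, 10, 10)))
))
seg <- segment_sinus(ph$stack, seed_point(14, 14, 14),
                     k = 100, polarity = "foreground_lt")
seg
#> <sinus_segmentation> 4169 voxels (k = 100, polarity = foreground_lt, layers = 0)

estimate_volume(seg$mask, voxel_side = 0.3, unit = "mm^3")
#> <volume_estimate> V = 113.7 +/- 24.1 mm^3  (interval [89.6, 137.7], L = 0.3)
#>   voxel counts: lower 3319 <= detected 4169 <= upper 5101
```

The detection recovers exactly the 4169 ground-truth cavity voxels, and
the reported interval brackets both that count and the continuous
sphere volume (4188.8 voxel³ ≈ 113.1 mm³): the ±24.1 mm³ error bar is
the method's honest statement of boundary uncertainty.

Cohort statistics on the shipped six-sample pilot series of pre/post
sinus volumes:

```r
cs <- cohort_summary(read.csv(pilot_cohort_path()))
cs
#> <cohort_summary> n = 6 paired samples (df = 5)
#>   relative change: mean 12.4%, SD 9.6 pp, 95% CI (2.3%, 22.5%)
#>   volumes: pre 16137.7 (SD 4511.7) -> post 14459.3 (SD 5167.6)
tidy(cs)$pct
#> [1]  1.1  4.8  8.8 11.8 23.2 24.5
```

`tidy()` / `glance()` return these as tibbles; `autoplot(cs)` draws the
pre/post bar chart, and `autoplot(seg, stack = ph$stack, slice = 14)`
overlays a detection on its slice.

A thin command-line front end ships at `inst/cli/sinusvol`
(subcommands `segment`, `volume`, `compare`, `cohort`, `validate`,
`phantom`).

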