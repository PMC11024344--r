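---
title: "Quantifying neurovascular niche organization with nichescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurovascular niche organization with nichescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescape)
```

## The measurement problem

Adult neural stem/progenitor cells (NSPCs) of the dentate gyrus live in a
narrow band — the subgranular zone (SGZ), about two cell-body widths wide —
threaded by a planar capillary network. A central question about this niche
is whether particular cell types sit closer to (or farther from) the
vasculature than chance would put them, and whether a perturbation (for
example, knocking down VEGF in NSPCs) changes that arrangement.

`nichescape` implements the measurement chain for this question on
multichannel fluorescence images:

1. **Vessel segmentation** (`segment_vessels()`): threshold a CD31-like
   endothelial channel and keep connected components that are large and
   elongated, discarding punctate background.
2. **Distance field** (`distance_field()`): the exact Euclidean distance
   (pixel centre to pixel centre) from every pixel to the nearest vessel
   pixel, in micrometres.
3. **Phenotyping** (`classify_cells()`): assign each Hoechst+ cell exactly
   one label from {RGL-NSC, IPC, NB, IN, astrocyte, other} from boolean
   marker calls and morphology flags, in a fixed priority order.
4. **Proximity vs a systematic random null** (`nearest_vessel_distance()`,
   `sample_random_null()`, `association_index()`): each phenotype's mean
   nearest-vessel distance is judged against the mean distance of random
   SGZ nuclei picked every ~100 µm along the SGZ midline. The signed
   difference is the association index: negative means closer than random
   (preferential vessel association), positive means farther.
5. **Group statistics** (`compare_groups()`): the animal is the
   experimental unit; per-animal means enter a Welch t test (two groups) or
   a one-/two-way ANOVA with Holm–Šidák-adjusted post hocs.

Two companion assay families are included: RNAscope-style puncta counting
per nucleus (`detect_puncta()`, `percent_difference()`) and in vitro
scratch/attachment metrics (`scratch_area()`, `ingression()`,
`count_nuclei()`, `retention()`, `paired_effect()`).

Because the original micrographs behind this kind of study are rarely
deposited, the package ships a fully seeded synthetic generator with ground
truth; every pipeline claim is validated by parameter recovery against that
truth.

## The synthetic niche generator

`generate_niche()` renders one animal's SGZ ribbon as a calibrated
two-channel image (CD31-like vessels, Hoechst nuclei) plus a cell table,
the midline, subregion polygons ({ML, GCL, SGZ, HL}), and a `NicheTruth`
record. The emulation targets the *statistical structure* of the
measurements, not photorealism:

- **Geometry.** A 4096 × 256 µm field at 1 µm/pixel represents the SGZ
  ribbon one mouse contributes across serial sections, collected into a
  single montage; the midline is a gentle curve at mid-height and the SGZ
  band extends ±7.5 µm around it. The ~4 mm of arc length gives ~40
  systematic null points per animal at the default 100 µm spacing, matching
  the scale of a per-mouse quantification.
- **Vasculature.** A planar Boolean process of smooth capillary segments
  (~120 µm long, radius 2.5 µm) whose centres scatter normally (SD 30 µm)
  around the midline and whose orientations follow the band's local
  direction with moderate jitter — capillaries run roughly in the plane of
  the band, so thresholded components stay individually elongated. The
  default density (0.018 µm/µm²) yields ≈ 8–9% CD31 area near the band.
- **Cell placement with known offsets.** The ground-truth quantity is the
  *offset*: a phenotype's mean nearest-vessel distance minus the
  random-nucleus baseline (the mean distance over band pixels). Cells are
  placed by sampling band pixels with a Gaussian distance-preference kernel
  `exp(-(d - mu)^2 / (2 sd^2))` whose centre `mu` is solved (by
  root-finding; the tilted mean is monotone in `mu`) so the expected
  distance equals `baseline + offset`. This realizes any feasible offset
  exactly in expectation while keeping a biologically sensible picture —
  each phenotype occupies a characteristic distance band (spread
  `placement_sd_um`, default 4 µm) rather than an arbitrary reweighting of
  the whole band. An offset outside the achievable distance range raises an
  error naming the phenotype and offset.
- **Cohorts.** `generate_cohort()` draws one animal-level normal deviate
  (default SD 0.8 µm) added to all of that animal's offsets, and derives
  per-animal seeds from the master seed via `seed_stream()`. With ~40
  RGL-NSCs and ~60 IPCs per animal, the simulated SEM of a group difference
  at 8–12 animals/group comes out near 0.6–1 µm, in the range of SEMs
  reported for such experiments; the between-animal SD was chosen for that
  plausibility, not fitted to any particular dataset.
- **Noise.** Channels are background plus signal with Gaussian read noise
  and a Poisson-like variance term scaling with signal; intensities are
  clipped to [0, 1] (the representable range of the 32-bit float TIFFs the
  package writes).

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify on real data: optical blur and z-projection artifacts,
uneven illumination, antibody background structure, true 3D vessel
topology, segmentation ambiguity at vessel boundaries, and observer
variability in marker calls. The generator validates the *estimators*; it
cannot validate image acquisition.

## Numerical and design choices

- **Distances** are Euclidean between pixel centres (EBImage's exact
  distance transform, cross-checked against exhaustive search in the test
  suite), read at the pixel containing each centroid without subpixel
  interpolation; the quantization bias is below half a pixel, well under
  the µm-scale effects of interest, and cancels in group differences.
- **Thresholds** default to Otsu's method on each channel's own range, with
  fixed numeric overrides for reproducibility (observer-set thresholds in
  the original workflows are unpublished). `scratch_area()` and
  `count_nuclei()` additionally require a minimum between-class contrast
  (default 0.25) before accepting an automatic threshold, because Otsu will
  happily split pure noise on a confluent or empty field.
- **Vessel filtering**: components must reach 20 µm² and a second-moment
  ellipse axis ratio of 2.5 by default. On rendered capillary networks the
  standalone default is conservative — junction-rich connected networks are
  elongated locally but their global moment ellipse can drop toward an
  axis ratio of 2 — so the end-to-end pipeline (`run_pipeline()`) uses 1.5,
  which still rejects punctate background (axis ratio ≈ 1). Both values are
  plain parameters.
- **Null sampling** starts at a seeded uniform phase offset in
  `[0, spacing)` rather than anchored at the midline start, avoiding phase
  artifacts; sample points with no nucleus within half a spacing are
  skipped with a warning; duplicate nuclei are collapsed.
- **Phenotype priority** RGL-NSC > IPC > NB > IN > astrocyte > other
  resolves multi-positive cells deterministically; the NB/IN boundary is
  morphological only (bipolar vs primary dendrite). Two rule sets ship
  (`reporter`, `antigen`) because reporter-based and antigen-based
  experiments identify the same phenotypes through different markers.
- **Post hocs** use the Holm–Šidák step-down (hand-computed, ~6 lines,
  since `p.adjust` offers no Šidák variant), a concrete choice for the
  generic "error-corrected post hoc tests" of such studies.
- **Paired wells**: attachment effects are computed per adjacent
  vehicle/treated well pair (`100 × (1 − treated/vehicle retention)`) and
  the treatment main effect is tested across experiment blocks by two-way
  ANOVA; pre/post images are assumed registered by acquisition position
  (an input contract — no registration is attempted).
- **Puncta counting** works on the 2D image: local maxima above threshold
  with a minimum peak separation (default 2 px), assigned to the containing
  nucleus. Spots merged below the separation count once; the generator
  records when it was forced to merge spots, so recovery tests can condition
  on unmerged nuclei.

## A worked recovery example

A small version of the central validation: simulate a cohort in which the
knockdown group's IPCs sit 3.5 µm farther from vessels than the control
group's, then recover that difference blind through the full pipeline.

```{r recovery, eval = FALSE}
offsets <- data.frame(
  phenotype = rep(c("RGL-NSC", "IPC"), each = 2),
  group     = rep(c("WT", "iKD"), 2),
  offset_um = c(2.5, 2.5, -1.6, -1.6 + 3.5))

res <- run_pipeline(list(
  simulate = list(groups = c("WT", "iKD"), n_animals_per_group = 8,
                  between_animal_sd_um = 0.8,
                  distance_offset_um = offsets),
  seed = 1))
res$group_differences
res$group_stats[["IPC"]]
```

The `group_differences` table reports the difference of group means of
per-animal mean distances; across seeds it centres on the configured
3.5 µm with a simulated SEM near 0.7 µm at this design size.

## Problem sizes used in the validation suite

The test suite and `scripts/acceptance.R` run entirely on synthetic data:
recovery cohorts at the original design sizes (8 vs 8 and 10 vs 12 animals)
on the default 4096 µm field; generator calibration and unit tests on
shorter 512–1024 µm fields; oracle-equivalence property tests on 200 random
rasters up to 64 × 64; type-I error on 1,000 simulated two-group
comparisons. These sizes were chosen so the whole suite completes in a few
minutes while keeping each check's sampling error well below the effect
sizes it examines.

## Known limitations

- 2D only: distances and contacts ignore the full 3D shape of cells and
  vessels (the measurement convention of single-plane/z-section
  quantification).
- Morphology flags (`radial_process`, `bipolar`, `primary_dendrite`) are
  inputs, not inferred from pixels.
- The association index treats the systematic null as exchangeable with
  phenotype cells; strong within-band density gradients of Hoechst nuclei
  would bias both similarly but are not modelled.
- Mixed-effects (cell-level) models are deliberately out of scope; the
  animal is the unit of analysis throughout.
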