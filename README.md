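# nichescape

Quantification of neurovascular niche organization in fluorescence
microscopy: how far do neural stem/progenitor cells (NSPCs) of the adult
dentate gyrus sit from the local vasculature, and does a perturbation
change that arrangement?

The package is written for labs quantifying marker-labelled cells around
segmented vessels in the subgranular zone (SGZ) — radial glia-like stem
cells (RGL-NSCs), intermediate progenitors (IPCs), neuroblasts, immature
neurons, astrocytes — and for the companion in vitro readouts (RNAscope
puncta per nucleus, scratch-wound ingression, attachment-assay retention).
Everything is validated against a seeded synthetic-niche generator with
known ground truth.

## The measurement model

For an animal with vessel mask `V` (thresholded, size- and
elongation-filtered CD31 channel) and Euclidean distance field
`D(p) = min_{v in V} ||p − v||` (µm), the per-cell measure is the distance
from the cell-body centre (Hoechst+ nucleus) to the nearest vessel. Each
phenotype `k` in animal `a` is summarized by its mean distance `d̄_{a,k}`,
judged against a **systematic random null**: random Hoechst+ nuclei picked
every ~100 µm along the SGZ midline, with mean `d̄_{a,null}`. The
association index

```
A_{a,k} = d̄_{a,k} − d̄_{a,null}
```

is negative when the phenotype sits closer to vessels than random
(preferential association) and positive when farther (dissociation).
Animals are the experimental unit: group comparisons are Welch t tests or
one-/two-way ANOVAs with Holm–Šidák post hocs on per-animal values.

Assay metrics follow the standard normalizations: scratch ingression
`1 − area(t)/area(0)` (0 = no ingression, 1 = complete closure), attachment
retention `post/pre` per well with paired adjacent-well effects
`100 × (1 − treated/vehicle)`, and puncta percent difference
`100 × (mean_ref − mean_a)/mean_ref`.

## Worked example

Simulate a two-group cohort (8 animals/group) in which the knockdown
group's IPCs are placed 3.5 µm farther from vessels than the control
group's (RGL-NSC offsets equal in both groups), then recover the difference
blind through segmentation → distance field → phenotyping → systematic
null → per-animal statistics:

```r
library(nichescape)

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
#>  phenotype comparison difference_um
#>    RGL-NSC   iKD - WT    -0.6464803
#>        IPC   iKD - WT     2.9064251

res$group_stats[["IPC"]]
#> Welch two-sample t test on factor(s): group
#>   term statistic       df            p
#>  group  5.678324 11.08997 0.0001383641
```

The IPC difference (2.91 µm here; configured truth 3.5 µm, simulated SEM
≈ 0.7 µm at this design size) is recovered and significant, while the
zero-offset RGL-NSC contrast stays at noise level. Per-animal association
indices show the expected biology — IPCs closer than random nuclei:

```r
head(res$per_animal[res$per_animal$phenotype == "IPC",
  c("animal_id", "group", "mean_dist_um", "null_mean_um",
    "association_index_um")], 3)
#>   animal_id group mean_dist_um null_mean_um association_index_um
#> 2    WT_m01    WT     4.348898     5.066861           -0.7179631
#> 4    WT_m02    WT     2.143236     5.522372           -3.3791358
#> 6    WT_m03    WT     4.894060     6.694102           -1.8000419
```

Single steps are available on their own (`segment_vessels()`,
`distance_field()`, `classify_cells()`, `sample_random_null()`,
`association_index()`, `percent_area()`, `overlap_fraction()`,
`detect_puncta()`, `scratch_area()`, `count_nuclei()`, `paired_effect()`),
and images, masks, cell tables and geometry round-trip through calibrated
32-bit TIFF, CSV and JSON (`read_image()`/`write_image()`,
`read_cell_table()`, `read_geometry()`).

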