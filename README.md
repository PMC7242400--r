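# lvcurve

Three-dimensional regional analysis of the left ventricle (LV) from
stacked short-axis cine contours. The package is aimed at cardiac imaging
researchers who already have endocardial/epicardial contours (e.g. from a
clinical segmentation tool) and want regional 3D shape and function
indices without any additional image acquisition.

## What it computes

From an ED/ES pair of contour stacks, `lvcurve` reconstructs
point-corresponded triangle meshes of both surfaces (slice misalignment
correction, Bézier contour up-sampling, spline lofting, thin-plate-spline
phase morphing) and evaluates, per AHA segment (1–16, true apex
excluded):

- curvedness `C = sqrt((k1^2 + k2^2)/2)` from the principal curvatures
  of the endocardial surface (mm⁻¹),
- wall thickness `WT` by normal-ray casting from the endocardium to the
  epicardium (mm),
- curvature-based wall stress index
  `sigma_i = R / (2·WT·(1 + WT/(2R)))` with `R = 1/C`,
- peak systolic wall stress
  `sigma_ES = 0.133 · (0.9·SBP) · sigma_i,ES` (1000 N/m²),
- area strain `AS = |ln(SA_ES/SA_ED)| · 100 %`,

plus global volumetrics (EDV, ESV, SV, EF, LV mass = 1.05 g/ml × shell
volume, BSA-indexed values). A statistics layer provides stratified
normal-range tables, one-way ANOVA with Bonferroni pairwise comparisons,
a two-way age×gender model (type-III tests, least-squares means), linear
age trends, Pearson correlations, and ICC / Bland–Altman / CV
reproducibility metrics.

Thick-walled ellipsoid phantoms with complete analytic ground truth are
built in (`phantom_spec()`, `generate_phantom_pair()`), so every stage of
the pipeline can be validated against closed forms.

## Worked example

A contracting prolate phantom (endocardium 45 × 25 mm, wall 5 mm,
uniform contraction λ = 0.8) through the full pipeline:

```r
library(lvcurve)
spec <- phantom_spec(a = 45, b = 25, wall_thickness = 5, contraction = 0.8)
ph   <- generate_phantom_pair(spec)
res  <- run_pipeline(ph$ed, ph$es,
                     list(subject_id = "demo", sbp = 120,
                          height = 170, weight = 70))

res$regional[res$regional$segment %in% c("1", "8", "14", "all"),
             c("segment","C_ED","C_ES","WT_ED","WT_ES",
               "sigma_i_ES","sigma_ES","AS")]
#>   segment   C_ED   C_ES WT_ED WT_ES sigma_i_ES sigma_ES    AS
#> 1 1       0.0302 0.0378  4.98  6.58      1.79      25.7  44.6
#> 2 8       0.0338 0.0422  4.89  6.71      1.55      22.3  44.6
#> 3 14      0.0503 0.0629  4.80  7.16      0.946     13.6  44.6
#> 4 all     0.0366 0.0457  4.90  6.78      1.49      21.4  44.6

res$global[, c("EDV", "ESV", "EF", "mass", "EDV_index")]
#>     EDV   ESV    EF  mass EDV_index
#> 1  58.8  30.1  48.8  37.0      32.3
```

Reading the output: curvedness rises from base (segment 1) to apex
(segment 14) because the surface tightens toward the apical cap, and
rises ED→ES as the cavity shrinks; the wall thickens ED→ES under the
incompressibility built into the phantom; the stress index falls where
curvature is high and the wall thick (Laplace behaviour). Under a uniform
contraction every segment's area strain is exactly
`200·ln(1/0.8) = 44.6 %`, and `EF = 100·(1 − 0.8³) = 48.8 %` — both
reproduced by the mesh pipeline to three digits. With real contours the
same call takes `read_contour_stack()` CSVs (one row per contour point,
header `subject,phase,slice,surface,point_index,x,y,z`) and a
demographics row.

A command-line front end is installed at
`system.file("cli", "lvcurve.R", package = "lvcurve")` with subcommands
`phantom`, `reconstruct`, `run`, `cohort` and `repro`.

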