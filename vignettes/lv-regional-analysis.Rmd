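---
title: "Curvedness-based LV regional analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvedness-based LV regional analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcurve)
```

## What the package computes

`lvcurve` reconstructs three-dimensional left-ventricular (LV) endocardial
and epicardial surfaces from stacks of manually or automatically segmented
short-axis cine contours, and derives regional shape and function indices
on the AHA 16-segment model:

* **Curvedness** $C = \sqrt{(k_1^2 + k_2^2)/2}$, where $k_1 \ge k_2$ are
  the principal curvatures of the endocardial surface. Unlike the mean
  curvature $H = (k_1+k_2)/2$ (zero at saddle points) or the Gaussian
  curvature $K = k_1 k_2$ (zero on parabolic lines), curvedness vanishes
  only where the surface is flat, so it is a faithful magnitude of local
  bending. Units mm$^{-1}$.
* **Wall thickness** $WT$: the length of a ray cast from an endocardial
  vertex along its outward normal to the first intersection with the
  epicardial surface. This 3D definition does not depend on a centre
  point or on the imaging frame and is shorter than any oblique 2D
  calliper distance. Units mm.
* **Wall stress index**
  $\sigma_i = \dfrac{R}{2\,WT\,(1 + WT/(2R))}$, the thick-walled Laplace
  form of pressure-normalised wall stress, with $R$ the inner radius of
  curvature. Dimensionless.
* **Peak systolic wall stress**
  $\sigma_{ES} = 0.133 \times SP \times \sigma_{i,ES}$ with
  $SP = 0.9 \times$ systolic blood pressure (mmHg); the factor 0.133
  converts mmHg to kN/m$^2$, so $\sigma_{ES}$ is reported in units of
  1000 N/m$^2$.
* **Area strain** $AS = \left|\ln(SA_{ES}/SA_{ED})\right| \times 100\,\%$
  per segment, the log-ratio of a segment's endocardial area between
  end-systole (ES) and end-diastole (ED). It aggregates circumferential,
  longitudinal and radial deformation into a single endocardial measure.
* **Global volumetrics**: EDV, ESV, SV, EF from basally-capped chamber
  volumes; LV mass $= 1.05\,\text{g/ml} \times$ (epicardial $-$
  endocardial ED volume); BSA-indexed variants.

A statistics layer reproduces the cohort analyses used for normal-range
studies: stratified mean $\pm$ SD tables, one-way ANOVA with Bonferroni
pairwise comparisons, a two-way age $\times$ gender model with
least-squares means, linear age trends and Pearson correlations, and
reproducibility metrics (ICC, Bland--Altman, coefficient of variation).

## Reconstruction pipeline

1. **Misalignment correction.** Breath-hold position differences translate
   slices in-plane. Each slice (endo and epi together) is translated so
   that the epicardial area centroids minimise
   $E=\sum_k \lVert c_k + s_k - \hat{c}(z_k)\rVert^2$ against a
   least-squares straight line $\hat c(z)$ through the centroids. A common
   translation or a linear-in-$z$ tilt of all slices is a rigid
   repositioning of the whole stack and is *unidentifiable* from the
   contours alone; the correction deliberately leaves that component
   untouched, and the phantom generator injects only the identifiable
   (detrended) component so recovery can be tested exactly.
2. **Bézier up-sampling.** Contours are interpolated with closed composite
   cubic Béziers (Catmull--Rom tangents, $C^1$ at joins) and re-sampled —
   at equal arc length for export, or at equal azimuth about the contour
   centroid for meshing. The contour is assumed star-shaped about its
   centroid, which holds for LV short-axis contours.
3. **Lofted meshing.** Each surface is meshed as `n_circumferential`
   $\times$ `n_longitudinal` structured rings joined by triangle strips,
   with an apical fan and an open base. Meridians are interpolated with
   cubic splines through the contour ring points *plus the apex point*;
   linear lofting would place intermediate rings on chords and inject an
   oscillation at the slice wavelength that corrupts curvature estimates.
   The apex vertex sits at the centroid of the most apical contour,
   offset apically by `apex_offset_fraction` (default 0.5) of the slice
   spacing — matching how a cine stack straddles the apex.
4. **Epicardial apical extension.** The contour dialect carries endo/epi
   pairs per slice, so the epicardium below the last endo-bearing slice is
   never sampled. Capping the epicardium at the same half-spacing offset
   as the endocardium would discard the apical myocardium (about 9% of
   shell mass on a sphere phantom). The epicardial apex is therefore
   placed one *reference wall thickness* below the endocardial apex —
   wall-thickness continuity — where the reference is the median ray-cast
   thickness over the mid-cavity rings of a provisional mesh. On phantoms
   this lands the epicardial apex on the analytic surface to
   $\sim$0.05 mm; on real anatomy it asserts that the apical wall is as
   thick as the mid wall, which slightly overestimates a thinned apex.
5. **Phase correspondence.** The ES meshes are produced by morphing the ED
   meshes with a 3D thin-plate-spline interpolant (kernel $U(r)=r$ plus an
   affine part) anchored at all ring vertices, with the ES ring positions
   as targets. Vertex count and connectivity are therefore identical
   across phases by construction, and segment labels transfer through the
   vertex index.

## Geometry estimators

* **Principal curvatures** are estimated per vertex by least-squares
  fitting of a height patch over the 2-ring neighbourhood in the local
  tangent frame (angle-weighted vertex normals). The patch contains
  linear, quadratic and cubic terms; curvatures come from the first and
  second fundamental forms of the fitted patch. The linear terms absorb
  the residual error of the estimated normal and the cubic terms absorb
  third-order surface variation. Both matter: with a pure quadratic
  patch, the ring adjacent to the apical fan on a 96 $\times$ 24 prolate
  phantom carries a 17--30% curvedness error; with the cubic-augmented
  patch the error is below 1% everywhere (median 0.4%).
* **Sign convention:** curvature is positive where the surface bends away
  from the outward normal, so a sphere seen from outside has
  $k_1 = k_2 = +1/r$. On the endocardium "outward" points away from the
  cavity, into the wall.
* **Excluded vertices.** The basal boundary ring, the apical fan ring and
  the apex vertex are excluded from all regional means: the curvature fit
  is biased at boundaries, and the true apex (segment 17) is not part of
  the 16-segment model.
* **$R = 1/C$.** The stress index needs an inner radius of curvature; the
  reciprocal of curvedness is used because it is well-defined at umbilic
  points, reduces to the radius on spheres, and keeps $\sigma_i$ a purely
  curvature-based index. A principal radius ($1/k_1$ or $1/k_2$) would be
  an equally defensible but less stable choice.
* **Area strain as a magnitude.** During contraction $SA_{ES} < SA_{ED}$,
  so the raw log-ratio is negative while the index is conventionally
  reported as a positive deformation magnitude (a healthy LV is expected
  around 60--80%); the absolute value reconciles the two.

## The 16-segment partition

The long axis runs from the basal plane (mean $z$ of the open base ring)
to the apex vertex and is divided into basal/mid/apical thirds by
normalised long-axis position. Basal and mid levels split into six
60° sectors, the apical level into four 90° sectors, by azimuth about the
long axis measured counter-clockwise (viewed from the apex) from
`reference_ray`. Anatomically the reference derives from the RV insertion;
the contour dialect cannot carry it implicitly, so it is a per-subject
input (default $+x$, adequate for phantoms). The atrioventricular-junction
definition of the long axis used with long-axis images is out of scope;
the aligned stack's $z$-axis is used instead and documented as an
approximation.

## The phantom generator

`phantom_spec()` describes a thick-walled truncated prolate spheroid:
endocardial semi-axes $(a, b, b)$, epicardial semi-axes enlarged by the
wall thickness, truncated at the equator by default, sliced by equally
spaced planes with the most apical slice half a spacing above the apex.
ES is a uniform endocardial contraction by $\lambda$; the ES epicardium is
scaled so that myocardial volume is conserved (incompressibility), which
fixes the ES wall thickness implicitly and yields a second analytic
check. Per-slice translations (misalignment) and radial point jitter
(noise) are seeded and recorded.

Defaults are chosen to emulate a healthy adult LV: $a = 45$ mm, $b = 25$
mm, $WT = 5$ mm (ED wall thickness $\approx$ 4.9 mm in healthy cohorts),
$\lambda = 0.71$ (EF $= 100(1-\lambda^3) \approx 64\%$, area strain
$= 200\ln(1/\lambda) \approx 68\%$), 12 slices and 96 points per contour.
Twelve slices is finer than the 10 mm clinical slice thickness; the
phantom's role is to be an *analytic oracle* for the reconstruction, so
its default sampling is chosen to expose method error rather than
acquisition error. Everything the phantom knows analytically is recorded
in its `GroundTruth`: injected shifts, per-slice curvedness and
normal-ray thickness, truncated cavity/shell volumes, EF and exact area
strain $200\ln(1/\lambda)$.

What the phantom deliberately does **not** emulate: trabeculation and
papillary muscles, regional wall-motion abnormalities, a saddle-shaped
mitral base, through-plane motion, and segmentation bias. Passing the
phantom suite therefore validates the *numerics* of reconstruction and
index computation, not robustness to real-world segmentation variability.

## Statistics layer choices

* **Two-way model.** `parameter ~ age_category * gender` with sum-to-zero
  contrasts and type-III F tests; least-squares means per gender are
  unweighted over age cells. Type III is the construct that matches
  LS means under unbalanced cells (the default cohort design is
  unbalanced: 30/36, 16/22, 30/23, 7/7 males/females per age category).
* **Linear trend** is the OLS slope of the parameter on *continuous* age
  with its t-test; an ordinal contrast over categories is a coarser
  alternative and was not used.
* **ICC** is the two-way mixed-effects, absolute-agreement,
  single-measurement form ICC(A,1), computed from the subjects
  $\times$ raters ANOVA mean squares — the standard choice for intra- and
  inter-observer CMR reproducibility. It is cross-checked in the tests
  against an independent implementation on a frozen dataset.
* **CV** uses the within-subject SD method,
  $100 \cdot (SD(d)/\sqrt{2})\,/\,\text{grand mean}$, with $d$ the paired
  differences.
* **BSA** uses the Mosteller formula $\sqrt{\text{height}\cdot
  \text{weight}/3600}$; Du Bois would shift indexed values by roughly 2%.

## Numerical tolerances and degenerate inputs

* Contours require $\ge 8$ points, simple (non-self-intersecting)
  polylines, counter-clockwise orientation viewed from the base (enforced
  on construction), strictly decreasing $z$, spacing uniform to 5%, and
  endo strictly inside epi per slice.
* The TPS system refuses duplicate landmarks (singular); the sphere
  identity morph reproduces ED vertices to machine precision.
* Rays that miss the epicardium (open base) are flagged and excluded;
  more than 5% missing among interior vertices is an error.
* Chamber volumes close the single boundary loop with a flat fan at the
  basal plane, mirroring Simpson planimetry.
* Sector assignment adds a $10^{-9}$ rad epsilon before `floor()` so
  structured-mesh columns that sit exactly on a sector boundary are
  assigned deterministically.

## Verification problem sizes

The test and acceptance suites run the full pipeline on a 96 $\times$ 24
sphere shell (r = 25 mm, WT = 5 mm) and a $\lambda = 0.8$ prolate
contraction phantom; curvature is validated on 2112 interior vertices of
the 45 $\times$ 25 mm prolate; misalignment recovery uses 20 seeds at
3 mm shift SD and 0.5 mm contour noise; ANOVA calibration uses 40
subjects per cell with 500--1000 replicates, and ICC recovery 1000
replicates of 20 pairs at true ICC 0.95. These sizes were chosen so every
check runs on a single CPU in minutes while keeping Monte-Carlo error
well below the asserted tolerances.

## Known limitations

* Wall thickness in the apical cap region inherits a few percent of error
  from the epicardial apical extension (exact on spheres; $\le$ 3.5% at
  the deepest interior ring of the prolate phantom).
* The reference ray defaults to $+x$; real AHA orientation requires the
  RV insertion landmark per subject.
* The basal plane is treated as flat and the LA/LV and LV/AO boundaries
  are not modelled; volumes therefore depend on the most basal contour
  placement, exactly as in slice-planimetry volumetrics.
* Curvedness is computed on the endocardium only; epicardial curvature
  indices are out of scope.
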