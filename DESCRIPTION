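Package: lvcurve
Title: Curvedness-Based Regional Analysis of the Left Ventricle from
    Short-Axis Contour Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs three-dimensional left-ventricular endocardial and
    epicardial surfaces from stacked short-axis cine contours (slice
    misalignment correction, Bezier contour up-sampling, lofted triangular
    meshing, thin-plate-spline phase correspondence) and computes regional
    shape and function indices on the AHA 16-segment model: curvedness from
    principal curvatures, ray-cast wall thickness, curvature-based wall
    stress index, peak systolic wall stress, and endocardial area strain.
    Includes thick-walled ellipsoid phantoms with analytic oracles for
    validation, global volumetrics (EDV, ESV, EF, mass), and a cohort
    statistics layer (stratified normal ranges, two-way age-by-gender
    ANOVA with least-squares means, linear trends, Pearson correlation,
    and ICC/Bland-Altman/CV reproducibility metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    emmeans,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
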