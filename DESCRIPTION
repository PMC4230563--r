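Package: shapepop
Title: Statistical Shape Models for Generating Populations of Organ Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds point-distribution models of closed organ surfaces
    (bladder-, rectum- and intestine-like shapes segmented for adaptive
    radiotherapy) from small training sets of triangle meshes or axial
    contour stacks, and draws new statistically representative geometries
    from them. The pipeline aligns training surfaces by scaling and
    translation, establishes dense point correspondence by closest-point
    search, lofts a NURBS reference surface through axial contours,
    deforms it to each training surface by iterative control-point
    warping, performs PCA on the corresponded resampled surface points,
    fits per-mode Gaussian-mixture densities to the training coefficients
    by EM, and synthesises new shapes by inversion sampling of the fitted
    densities. Includes a synthetic-population generator with known
    ground-truth deformation modes for validation, and readers/writers
    for PLY, OBJ, STL and a documented JSON contour format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), mclust, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
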