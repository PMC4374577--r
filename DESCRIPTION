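Package: cdt
Title: Constrained Distance Transforms for Landmark-Based Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based non-rigid registration of 2D and 3D biological
    images using radial basis function (RBF) displacement transforms in which
    inter-point distances are constrained to geodesics inside a simplicial
    mesh conforming to the object's domain (the constrained distance
    transform, CDT). Provides domain/value-table image objects with PNG, TIFF
    and NIfTI-1 input/output, conforming triangle and tetrahedral mesh
    generation from binary masks plus Gmsh/VTK/OFF import and export, a
    two-stage geodesic distance solver (nearest-neighbour line-of-sight
    initialisation followed by mesh-based fast marching with virtual-node
    handling of obtuse elements), morphological raster distance baselines,
    thin-plate-spline, multiquadric, inverse multiquadric and Wendland RBF
    fitting and evaluation, mesh-based pull-back and forward image
    resampling, synthetic corridor and embryo-tail fixtures with analytic
    geodesic oracles, and the evaluation studies built on them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    RNifti
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
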