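Package: bronchoplan
Title: Airway Tree Construction, Route Planning and Virtual Bronchoscopy
    Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a bronchoscopy planning workflow for
    peripheral lung lesions. Builds a branch model of the airway tree from
    centerline points, computes the centerline route from the top of the
    trachea to the airway position closest to a pinpointed target, and
    generates virtual-bronchoscopy geometry: smoothed centerlines, synthetic
    tube meshes with generation-dependent radii, fly-through camera paths
    with parallel-transport up vectors, and axis-aligned cut planes.
    Includes a stand-in airway extraction stage (seeded region growing,
    3D topological thinning, isosurface extraction) and a generator of
    ground-truth bifurcating airway phantoms (tree, binary mask, pseudo-CT)
    so the whole pipeline runs and is testable without patient data.
    Reads and writes DICOM CT series, NIfTI, MetaImage, CSV/VTP centerlines,
    STL/PLY meshes and JSON trees, targets, routes and camera paths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
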