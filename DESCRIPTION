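Package: mandimorph
Title: Landmark-Based Mandibular Morphometry and Reconstruction-Guide Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric morphometry of the human mandible from triangle surface
    meshes (STL) and named 3D landmarks: an anatomical reference frame, planar
    silhouette projections, convex-hull tangent and bisector constructions
    (gonion, basilar and alveolar inflexion points), and a standardized
    ten-measurement protocol (six bilateral, four single). Includes a
    parametric synthetic mandible generator with closed-form ground truth for
    validation, cohort descriptive statistics (coefficient of variation,
    bilateral symmetry, sexual dimorphism with a normality gate), intraclass
    correlation reliability with Rosner classification, and planning of
    fibular osteotomy wedge angles for standardized anterior mandibular
    reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
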