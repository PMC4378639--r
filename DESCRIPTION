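Package: laminametrics
Title: Leaf Lamina Morphometrics, Curvature Proxies, and Proliferation
    Front Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for characterising leaf lamina shape and
    cell-proliferation patterning. Implements planar shape metrics (length,
    width, perimeter, area, leaf index) from outline polygons, the
    scale-free curvature proxy P/sqrt(A) together with an elliptical-leaf
    null model, intrinsic surface metrics on triangulated laminae of
    positive, negative, or zero Gaussian curvature, binned medio-lateral
    mitotic-arrest-front profiles from cell-level reporter data,
    proliferation-zone length dynamics, growth kinetics from width time
    series, cell-size and cell-count estimation, and segmentation-based
    quantification of reporter-stained tissue images. A synthetic-data
    module generates leaf outlines, curved surface meshes, cell lattices
    with Bernoulli reporter status, growth series, and rendered stain
    images so that every stage of the pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    igraph,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
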