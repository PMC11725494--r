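Package: spatialkit
Title: Unified Containers, Transformations, Queries and Aggregation for
    Spatial Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A unified data model for spatial omics at desk scale. Represents
    a dataset as a named collection of five element kinds (images, label
    masks, points, shapes and annotation tables), attaches algebraic
    coordinate transformations so heterogeneous modalities can be aligned
    into common coordinate systems, estimates affine and similarity
    transforms from paired landmarks, supports spatial queries (bounding box
    and polygon) and cross-element aggregation (point counts and area-weighted
    category fractions at capture locations), and persists collections in a
    hierarchical Zarr-style store with OME-NGFF-aligned raster metadata,
    multiscale pyramids and lazy raster access. Deterministic synthetic-data
    generators provide download-free test fixtures, including an aligned pair
    of modalities with known ground-truth transform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    EBImage,
    jsonlite,
    Matrix,
    methods,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
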