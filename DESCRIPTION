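Package: ibsmorph
Title: Adjacent-Voxel Structural Pattern Analysis and Information-Based
    Similarity for Grey-Matter Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes 3D grey-matter density volumes into voxel-wise
    structural pattern indices (6-neighbour intensity relations, 64
    codes), compares brain regions with an entropy-weighted rank
    distance (information-based similarity), quantifies per-region
    structural randomness against spatially shuffled surrogates, and
    provides the group-comparison and cognition-regression layer for
    atlas-parcellated cohorts. Includes a synthetic phantom generator
    so every stage is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
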