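Package: sightshed
Title: Quantifying the Shielding Effect of 3D Environments from LiDAR Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how a three-dimensional environment, reconstructed as a
    terrestrial-LiDAR point cloud, occludes an observed target from an observer.
    The observed body is simplified to a vertical minimum enclosing rectangle
    placed at polar sample positions around the observer; occluding points are
    projected onto the rectangle along the line of sight, rasterized into a
    binary occlusion image, and summarised as a visibility index. Both a
    terrain-normalized scenario (ground flattened to height zero) and a
    terrain-preserving scenario (an elevation-angle-tilted projection slab) are
    supported, together with ground classification, height normalization,
    ground densification, seeded synthetic forest scenes, a logarithmic
    visibility-distance model, and visibility-deviation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    FNN,
    grDevices,
    graphics,
    interp,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
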