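Package: olivecanopy
Title: Crown and Shadow Based Canopy Biovolume from Orchard Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating per-tree canopy biovolume in olive orchards
    from nadir multispectral imagery. Provides a synthetic orchard scene
    generator with known per-tree geometry, vegetation-index band arithmetic
    (NDVI, GNDVI) with exact area-weighted resolution degradation, VGG Image
    Annotator (VIA) 1.x polygon annotation input/output, a deterministic
    threshold-based reference segmenter for crown and shadow instances,
    IoU-based detection evaluation (precision, recall, F1), a NOAA-style
    solar position algorithm, and shadow-length tree-height and cylinder
    biovolume geometry with an overall-accuracy statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    mgcv,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
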