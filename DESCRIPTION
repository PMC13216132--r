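Package: mosaictopo
Title: Topographic Drivers of Forest-Savanna Mosaic Configuration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether topography explains where forest
    (closed) and savanna (open) tree cover sit within mosaic landscapes.
    Derives multi-scale topographic position indices, slope and aspect
    components from elevation grids; tiles rasters into landscapes and
    classifies them by tree-cover composition; fits seeded random-forest
    classifiers of pixel cover state at regional and per-landscape scale;
    summarises feature effects with accumulated local effects (ALE) curves
    and their Spearman-based effect directions; and generates synthetic
    terrain and vegetation rasters with known ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
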