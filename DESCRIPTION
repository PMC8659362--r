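Package: riverpad
Title: Colorimetric Readout and Mapping of Paper-Based Phosphate Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for citizen-science phosphate monitoring of
    freshwater with paper-based analytical devices (PADs). Generates
    ground-truthed synthetic device photographs with phosphomolybdenum-blue
    colour-development kinetics, locates the printed reaction zones in a
    photograph, computes internally standardised average relative
    intensities (ARI), fits concentration calibrations with limits of
    detection and quantification, classifies readings into the four map
    brackets used for public reporting, and aggregates geolocated sampling
    records into GeoJSON map layers and seasonal summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
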