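Package: ecoclimex
Title: Process-Based Ecoclimatic Suitability Modelling with Taguchi
    Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A CLIMEX-style process-based bioclimatic niche model driven by
    gridded monthly climate normals: trapezoidal temperature and soil-moisture
    growth responses, a weekly soil-moisture bucket water balance,
    threshold-based cold/heat/wet stress accumulation, and the 0-100
    Ecoclimatic Index with a four-way suitability classification.  Includes a
    seeded synthetic-climate generator emulating the structure of 0.5 degree
    global normals, latitude-aware area accounting per suitability category,
    occurrence-record curation and validation against suitability rasters, and
    a mixed-level L54 (2^1 x 3^25) orthogonal-array Taguchi sensitivity
    analysis that ranks the model's fourteen species parameters by
    larger-the-better signal-to-noise main effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
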