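Package: hsmeval
Title: Evaluation and Ensemble Mapping of Pre-Existing Habitat Suitability Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing and combining pre-existing (contractor-delivered)
    continuous habitat-suitability models for rare species. Implements a
    construction-audit rubric with three occurrence-data exclusion gates,
    quality control of element-occurrence polygons (accuracy-class filtering,
    internal centroids, maximal spatial thinning at a minimum separation
    distance), capture-rate-driven recalibration of suitability thresholds,
    union/overlay mapping of probable and potential suitable habitat with
    per-pixel model counts and standardized suitability scores, multispecies
    stacking, and area summaries by management overlay. Includes a seeded
    synthetic-data generator (landscapes, occurrence records, contractor-style
    model variants) so the full pipeline can be exercised without proprietary
    inputs. Raster I/O uses ESRI ASCII grids and vector I/O uses GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
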