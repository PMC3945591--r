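Package: hazex
Title: Multi-Hazard Population Exposure Assessment on Gridded Data
Version: 0.1.0
Authors@R:
    person("Water and Climate", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds relative-frequency decile grids for cyclone, drought and
    flood hazards from event records, classifies grid cells as urban or rural
    using country-specific population-density thresholds matched to tabulated
    urban proportions, and computes, ranks and stratifies country-level
    average population exposure scores (total, urban, rural, and by human
    development class). Includes a lightweight geographic raster data model
    with ESRI ASCII grid I/O, a seeded synthetic-world generator for fully
    reproducible end-to-end testing, and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
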