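Package: vertcol
Title: Serial Variation and Taphonomic Distortion in Vertebral Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying serial variation in the articular-facet
    aspect ratios of vertebral columns, with an emphasis on detecting
    taphonomic distortion in fossil (sauropod) necks. Provides a measurement
    data model and CSV schema for per-vertebra facet extents, two
    serial-variation metrics (mean absolute first difference and mean
    normalized first ratio of consecutive vertical/horizontal aspect ratios),
    elongation indices (EI and aEI) with a crush-corrected cotyle-height
    estimator, a seeded synthetic-column generator with a parametric
    oblique-crushing model for end-to-end testing of metric behaviour, and a
    completeness catalogue of published sauropod neck specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
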