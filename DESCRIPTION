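Package: dida
Title: Digital Image Disintegration Analysis for Fast-Disintegrating Tablets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts video recordings (as ordered PNG/TIFF frame stacks) of a
    tablet disintegrating in a small dark vessel into quantitative
    disintegration profiles. Mean grey values (MGV) over a fixed region of
    interest are background-corrected and normalized against an intact-tablet
    reference so that the intact tablet reads 100 percent and cleared medium
    reads 0 percent; values above 100 percent indicate swelling. Profiles are
    summarized at pharmacopoeial timepoints (10 s, 30 s, 3 min), classified
    into instant, fast, prolonged, partial or swelling behaviour, and compared
    across conditions with Welch t-tests from summary statistics. A synthetic
    recording simulator with closed-form disintegration kinetics provides
    ground truth for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
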