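Package: elastoscore
Title: Color-Map Grading of Cervical Ultrasound Elastograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for grading color-coded cervical strain elastograms on the
    1-5 blue/green/red area-fraction scale used in ultrasound elastography of
    the cervix. Provides a seeded synthetic-elastogram generator with known
    color composition, hue-based pixel classification and area-fraction
    measurement, the rule-based 1-5 elasticity score, a from-scratch
    sigmoid-gated LSTM sequence scorer trained to emulate the rubric on
    synthetic images, and cohort analytics for pre/post treatment score
    comparisons (group totals, per-patient mean change, confusion-matrix
    accuracy, one-way analysis of variance), plus a reproducible end-to-end
    pipeline with PNG/CSV/JSON file contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
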