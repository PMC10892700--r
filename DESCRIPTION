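Package: ergofield
Title: Ergonomic Risk Scores and In-Shoe Plantar Pressure Analytics for
    Occupational Field Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing wearable-sensor recordings from occupational
    field studies: continuous RULA and CUELA ergonomic risk scoring from
    joint-angle time series, six-region in-shoe plantar pressure kinetics
    (mean pressure, peak pressure, pressure-time impulse, loaded time),
    Borg CR-10 body-map and fatigue VAS composites, and repeated-measures
    comparison of pre- versus post-shift sessions and left versus right
    foot sides (rmANOVA with Greenhouse-Geisser correction, partial eta
    squared, Bonferroni post hocs).  A seeded synthetic work-shift
    generator produces complete angle, insole and survey datasets so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
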