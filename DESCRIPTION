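Package: swayval
Title: Instrument Validation of Head-Mounted Position Tracking Against
    Force-Plate Posturography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for validating consumer head-mounted (virtual reality)
    position tracking as a low-cost alternative to force-plate center-of-
    pressure (COP) recording in static balance assessment. Provides a
    stochastic generator for paired dual-rate postural-sway cohorts
    (force plate at 200 Hz, headset at 10 Hz) with controllable between-
    and within-subject variance structure; the standard stabilogram
    summary measures (normalized path length, root mean square,
    peak-to-peak); two-way mixed-effects intraclass correlation
    coefficients with F-pivot 95% confidence intervals and the usual
    reliability classification bands; univariate regression of COP
    metrics on headset metrics with coefficients of determination; and a
    one-command pipeline that assembles reliability and agreement report
    tables from a cohort directory or a simulation configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
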