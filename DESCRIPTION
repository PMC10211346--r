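Package: betaxplore
Title: Sensor-Level Beta-Band Dynamics of Explorative and Exploitative Choice
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic re-implementation of a sensor-level
    MEG analysis of beta-band (16-30 Hz) power during explorative versus
    exploitative choices in a two-alternative probabilistic reward task.
    Includes a task and agent simulator with quasirandom interleaved outcome
    sequences, the learning-criterion trial taxonomy (HP / pre-LP / LP /
    post-LP), a synthetic multichannel epoch generator with injectable
    event-related beta desynchronization and synchronization effects, DPSS
    multitaper beta-band power with fixed-condition decibel baselining,
    two-stage single-trial linear mixed-model screening (Benjamini-Hochberg
    FDR over the sensor-by-time grid, rule-based cluster extraction) and
    effect-level mixed models with Tukey HSD contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
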