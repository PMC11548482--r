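Package: glowqc
Title: Quality Control of Thermoluminescent Dosimeter Glow Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filters and classifies anomalous glow curves from LiF:Mg,Ti
    thermoluminescent dosimeter (TLD) readers. Implements a staged pipeline:
    elapsed-time background subtraction, reporting-level filtering, a shallow
    neural-network shape filter on normalized channels plus distribution
    moments, crystal dose-ratio plausibility checks against a radiation-field
    ratio table, a rule cascade that classifies anomalies into five classes
    (elevated low/high-temperature background, abnormal width, shifted peak,
    spikes, and a residual class), automatic correction of elevated-background
    curves, and append-only per-dosimeter statistics with distribution
    reports. Ships a synthetic glow-curve simulator with labeled anomaly
    injection for training and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
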