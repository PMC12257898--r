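Package: spotpet
Title: Spot-by-Spot In-Beam PET Range Verification for Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for instantaneous proton range verification from
    short-lived positron emitter (12N) PET imaging at the pencil-beam-spot
    level. Provides a synthetic generator of per-spot list-mode coincidence
    data and pencil-beam-scanning delivery logs, time-histogram segmentation
    of the beam time structure, mid-plane line-of-response image
    reconstruction, weighted sigmoid fitting of the distal activity fall-off
    to estimate the positron activity range, decay-weighted activity
    prediction from per-isotope production maps, and detection of range
    shifts with combined uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
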