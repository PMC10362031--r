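Package: scgvision
Title: Contactless Seismocardiography from Chest Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Recovers sub-pixel chest-wall displacement from video by
    Lucas-Kanade template tracking, converts the tracked motion to
    calibrated seismocardiogram (SCG) acceleration signals, and validates
    vision-based SCG against reference accelerometer and ECG recordings
    using a dynamic-time-warping similarity index, magnitude-squared
    wavelet coherence, and heart-rate agreement statistics. Ships a
    synthetic-scene generator that renders textured targets moving with
    cardiac-like waveforms so the whole pipeline can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
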