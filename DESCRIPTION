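Package: blinkscope
Title: Quantified Analysis and Visualization of Eye Blinking from
    High-Frame-Rate Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts individual eye blinks from high-frame-rate
    grayscale video, quantifies the shape and position of the upper
    eyelid in every frame, renders each blink as a single normalized
    image (a kymograph-like blink matrix), segments each blink into
    closing, complete-closed and opening phases, classifies blink
    patterns (normal, incomplete, consecutive), and computes blink
    parameters such as rate, duration, phase ratios and eyelid speeds.
    Includes a synthetic eye-video generator with exact ground truth so
    every stage of the pipeline can be validated without human-subject
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
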