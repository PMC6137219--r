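Package: ivsn
Title: Zero-Shot Invariant Visual Search with Target-Modulated Attention Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates human-like fixation sequences for visual search on
    arbitrary images. A convolutional feature hierarchy (the "ventral stream")
    processes both the target cue and the search image; the target's top-level
    features act as a convolution kernel over the search image's features to
    produce a top-down attention map, and a winner-take-all rule with
    inhibition of return turns that map into a scanpath. Includes model
    variants (finite inhibition of return via a fitted memory function,
    recognition-based stopping, saccade-size constraints), null models
    (chance, sliding window, pixel template matching, a minimal bottom-up
    saliency baseline, random-weight networks), synthetic stimulus and
    scanpath generators, fixation-table preprocessing, and evaluation metrics
    (cumulative search performance, fixation-count consistency, mean-shift
    plus string-alignment scanpath similarity, revisit-probability and
    saccade-amplitude model fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
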