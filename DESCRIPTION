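Package: vibroscout
Title: Vibroacoustic Detection of Woodboring Insect Larvae in Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and counts the short broadband micro-vibrations
    (impulses) that woodboring larvae produce when fracturing wood fibers,
    from vibrational recordings taken inside tree trunks. Implements a
    two-stage detector: an energy gate that discards recordings dominated
    by broadband interference (rain, wind), followed by moving-average
    envelope extraction, segment-wise adaptive noise floors and
    duration-gated impulse counting. Includes a synthetic vibroscape
    generator with ground truth for validation, count-regression and
    binary-classification evaluation metrics, tree-level monitoring
    analytics (cumulative impulse curves, hourly activity, duration
    histograms, infestation classification), and a command-line interface
    for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
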