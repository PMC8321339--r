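Package: frozenframes
Title: Frozen-Frame Detection for Micro-Expression Spotting in Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fast preprocessing for facial micro-expression (ME) spotting.
    Detects "frozen frames" -- short intervals of concealed, motionless pose
    that flank micro-expressions -- by separable spatio-temporal low-pass
    filtering of a grayscale frame stack and analysis of the local minima of
    the per-frame spatial standard deviation of the filtered sequence.
    Selected minima are expanded into small groups of frames (GOFs) that a
    downstream spotting algorithm can restrict itself to. Includes the
    matching temporal high-pass (derivative) filter pair used to verify the
    stillness interpretation of the minima, frame-level ROC/AUC evaluation
    against onset/offset annotations, and a seeded synthetic video generator
    with planted motion bursts and frozen plateaus for ground-truthed
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
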