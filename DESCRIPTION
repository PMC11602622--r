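Package: calcitune
Title: Calcium-Imaging Analysis of Odorant-Receptor Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing and statistical pipeline for insect olfactory
    calcium-imaging screens: delta-F/F0 and ratiometric (Fura-2 340/380)
    trace processing with photobleaching correction, response-amplitude
    quantification, lifetime-sparseness tuning-breadth measures,
    response-spectrum clustering, Hill dose-response (EC50) fitting, the
    accompanying hypothesis-testing layer (Friedman, repeated-measures ANOVA
    with Greenhouse-Geisser correction, Kruskal-Wallis, Dunn and Dunnett post
    hoc tests), and minimal single-sensillum spike-rate summaries. Includes a
    synthetic-data generator with planted ground truth so every stage of the
    pipeline can be validated by amplitude, EC50 and rate recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    ape,
    signal,
    minpack.lm,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
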