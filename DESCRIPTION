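Package: leafdrought
Title: Leaf Color, Pigment, Anatomical and Hydraulic Trait Analysis for
    Factorial Drought Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing autumn leaf-coloration responses to drought
    in a factorial (treatment x sampling-period x replicate) pot experiment.
    Derives replicate-level traits from raw measurements: CIELAB color
    aggregation, spectrophotometric chlorophyll/carotenoid/anthocyanin
    contents and ratios, anatomical thickness indices including the
    palisade-to-spongy ratio, Hagen-Poiseuille leaf hydraulic conductance
    from petiole vessel anatomy, epidermal (minimum) conductance from the
    linear tail of fresh-weight drydown curves, and pressure-volume curve
    parameters (osmotic potential at full turgor, turgor loss point).
    Provides the matching inference layer: one-way ANOVA from raw data or
    printed mean/SE summaries, Duncan's multiple range test with compact
    letter displays along both factorial axes, Pearson correlation matrices,
    and permutation-tested random-forest variable importance (%IncMSE) with
    backward predictor selection. A seeded synthetic-data module emulates
    the full experiment so every stage can be exercised and validated at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
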