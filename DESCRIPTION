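Package: boutonca
Title: Detection and Photobleaching Analysis of Presynaptic Calcium Transients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying fluorescence signals from single presynaptic
    boutons imaged at 10 Hz: moving-baseline threshold detection of evoked and
    spontaneous calcium (or glutamate) transients, per-event kinetics, baseline
    level and trace-noise quantification, epoch comparisons under treatments,
    and use-dependent photobleaching / fluorescence-recovery analysis. Includes
    a seeded generative simulator of bouton fluorescence (three signal classes,
    shot-noise baseline, use-dependent bleaching with slow pool exchange) and a
    renderer of synthetic image stacks, so the full pipeline from movie to
    cohort summary is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
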