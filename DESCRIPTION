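Package: somnarc
Title: Sleep Architecture, Spectral Metrics and Motion-Based Sleep Inference
    for Rodent Rocking-Stimulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent sleep studies using vestibular
    (rocking) stimulation. Provides epoch-wise hypnogram handling and
    architecture metrics (state amounts, time courses, episode segmentation
    and duration histograms, brief-arousal detection), per-epoch EEG power
    spectra with slow-wave activity (SWA), slow-wave energy (SWE) and beta
    band summaries, motion-based sleep inference via an immobility-run rule
    with a sleep fragmentation index, baseline-normalized longitudinal
    day-by-cycle summaries for block designs, behavioral and blot-densitometry
    scoring, and a comparison layer with Sidak-corrected bin-wise spectral
    tests. A semi-Markov synthetic-data generator with rocking-entrained NREM
    oscillations and habituation dynamics makes every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
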