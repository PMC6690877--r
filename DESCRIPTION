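Package: midecay
Title: Mutual Information Decay Analysis of Vocal Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sequential dependencies in symbolic vocal
    sequences such as birdsong syllable transcripts and phonetically
    transcribed speech. Estimates shuffle-corrected mutual information
    between sequence elements as a function of their sequential distance
    using the Grassberger entropy estimator, fits exponential, power-law
    and composite decay models to the resulting curves in log space,
    compares them with small-sample corrected Akaike weights, and locates
    the curvature "knee" marking the transition from Markovian
    (exponential) to hierarchical (power-law) decay. Includes seeded
    generative grammars (Markov, recursive hierarchical, and their
    combination) for simulation studies, shuffle-based controls that
    isolate within-unit versus between-unit information, and a
    config-driven analysis pipeline.
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
    jsonlite,
    minpack.lm,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
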