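Package: scribeye
Title: Keystroke and Gaze Analysis of Written Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the moment-by-moment dynamics of written
    composition from keystroke logs and eye-movement records. The package
    replays editor event logs into a time-indexed document model, maps
    fixations onto the text as it existed at fixation time, classifies
    inter-keystroke transitions by text location (before sentence, before
    word, within word) and by writing versus editing, detects lookback
    events by an operational four-criterion definition, computes text
    measures including MTLD lexical diversity, and fits Bayesian
    hierarchical models: a two-component lognormal mixture for
    inter-keystroke intervals with by-participant mixing proportions, and
    binomial, lognormal and negative-binomial mixed models, with
    Savage-Dickey Bayes factors. A synthetic-session generator produces
    event logs and fixation streams with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
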