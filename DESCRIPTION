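Package: narrafnirs
Title: Event-Locked fNIRS and Narrative-Language Analysis of Trauma Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking word use in spoken trauma narratives to
    event-locked prefrontal fNIRS activation. Provides a seeded synthetic
    cohort generator (subjects, timed transcripts, prosody tracks and
    two-wavelength optical-density recordings), optical preprocessing
    (motion correction, modified Beer-Lambert inversion, zero-phase
    band-pass filtering, rest-referenced z-scoring), lexical and prosodic
    feature extraction (Honore's R, emotion-category rates, pitch
    declination, pause counts), a trainable hierarchical bidirectional
    recurrent tagger for emotional and factual vocabulary, event-locked
    window analysis with channelwise Mann-Whitney tests under FDR control,
    time-course characterization (latency, slope, peak, Spearman trend),
    and normality-gated group statistics with effect sizes and a priori
    power computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
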