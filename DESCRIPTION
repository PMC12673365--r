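Package: timbrecolor
Title: Timbre-Color Synesthesia Scoring, Stimulus Synthesis and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for timbre-color synesthesia experiments.
    Provides objective synesthete classification from repeat color picks via
    CIEDE2000 color-difference consistency scoring; additive synthesis of
    loudness-matched harmonic-plus-noise instrument tones with the two timbre
    manipulations used in such studies (stepwise removal of the lowest
    partials and stage-wise spectral morphing between instrument pairs);
    extraction of the three audio descriptors the analysis rests on (spectral
    centroid, tone-network harmonicity strength, BS.1770 percussive loudness)
    together with harmonic-percussive source separation; correlation and
    morph color-distance trend statistics; and a calibrated synthetic-cohort
    generator that emulates synesthete and non-synesthete response behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
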