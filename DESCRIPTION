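Package: emochoice
Title: Predicting Individual Food Choice from Liking and Food-Evoked
    Emotions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting individualized food choice from liking
    ratings and emotion-profiling data (PrEmo, EsSense Profile and similar
    instruments). Emotion scores are demeaned within participant and
    decomposed by singular value decomposition into valence and arousal
    components; choices among alternatives are modelled with conditional
    (multinomial) logit models estimated by Newton-Raphson with analytic
    derivatives. Includes likelihood-ratio model ladders with forward
    selection, McFadden's adjusted pseudo r-squared, the Hausman-McFadden
    test of independence of irrelevant alternatives, a leave-one-out
    cross-validation that re-learns the principal-component rotation per
    fold and scores prediction by the rank of the chosen product, and a
    synthetic-data generator with known ground truth for validating every
    stage of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
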