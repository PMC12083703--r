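Package: prefalign
Title: Preference-Learning Dataset Construction, Odds-Ratio Alignment
    Objectives, and Ranked-List Evaluation for Biomedical Label Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring knowledge from a ranked-output classifier
    to a generative language model via preference optimization. Builds
    chosen/rejected preference records from ranked label predictions with a
    truth-first guarantee, implements the ORPO (odds-ratio) and DPO (direct
    preference optimization) objectives as pure functions over sequence
    log-probabilities, and grades free-text ranked-list responses with
    fuzzy string matching to compute hallucination-free accuracy, Top-N and
    Top-1 accuracy, and the Coverage-Avoidance Rate (CAR). Includes a
    calibrated synthetic upstream-classifier simulator, a patient-record
    generator built on phenotype-term vocabularies, and a character-level
    toy language model for end-to-end alignment experiments on a desktop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
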