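Package: imcpattern
Title: Pattern Analysis of Knee Isokinetic Moment Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Qualitative analysis of knee-extensor isokinetic moment curves
    (torque versus joint angle at constant angular velocity). Simulates
    torque-angle traces carrying the irregular morphologies seen after knee
    injury (a recovering pre-peak "valley" notch, a sharp non-recovering
    post-peak "drop", and mid-curve "shaking" flutter), preprocesses raw
    repetitions onto a 1-degree grid with peak normalization, classifies
    curves with a deterministic breakpoint rule set and a three-repetition
    consistency criterion, quantifies rater agreement with Cohen's kappa,
    fits the multinomial logistic association between curve pattern and
    structural knee injury, and evaluates the resulting pattern-to-injury
    predictor (confusion matrix, per-class recall/precision/F1,
    macro-averaged F1, accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
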