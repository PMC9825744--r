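Package: dxagent
Title: Decoupled Symptom-Inquiry and Disease-Diagnosis Dialogue Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating task-oriented diagnostic
    dialogue agents that decouple symptom inquiry from disease diagnosis.
    A causal (unidirectional) self-attention decoder treats symptoms as
    tokens and learns a next-symptom inquiry policy by maximum-likelihood
    pre-training followed by REINFORCE policy-gradient training against a
    patient simulator; an order-invariant bidirectional encoder classifies
    the collected positive/negative symptom set into diseases, sharing the
    symptom and attribute embedding tables with the decoder. A confidence
    threshold on the classifier governs the switch from inquiry to
    diagnosis. The package includes structured consultation-record I/O, a
    disease-conditional synthetic data generator with an exact Bayes
    oracle, disease-symptom co-occurrence rewards and a rule-based inquiry
    baseline, symptom-recall and diagnostic-accuracy metrics, and
    SVM-based accuracy-bound estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
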