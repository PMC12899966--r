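Package: arkemo
Title: Prototype-Based Facial Emotion Recognition from ARKit Blend Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing facial-expression recordings exported as
    per-frame ARKit blend shape coefficients (52 named activations in [0,1]).
    Implements an interpretable, training-free emotion classifier that matches
    subject-standardized blend shape vectors against EMFACS-guided emotion
    prototypes by cosine similarity, alongside a mean-activation baseline.
    Includes the full preprocessing chain (frame-rate harmonization,
    subject-wise z-scoring, sustained-phase selection), descriptive analyses
    (blend shape ranges, opposite-pair overlap, facial-region co-activation),
    evaluation machinery (accuracy, row-normalized confusion matrices,
    one-vs-rest ROC/AUC, Krippendorff's alpha for rater agreement), and a
    seeded synthetic cohort generator that emulates a posed-expression
    recording protocol for end-to-end testing without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
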