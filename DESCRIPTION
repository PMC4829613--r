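Package: lepnorm
Title: Spontaneous-EEG Normalization of Laser-Evoked Responses and
    Cross-Individual Pain Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for single-trial analysis of laser-evoked EEG magnitudes
    and cross-individual pain prediction. Each trial's pre-stimulus
    (spontaneous) and post-stimulus (pain-evoked) segments are reduced to
    root-mean-square magnitudes; evoked magnitudes are normalized as z-scores
    of the same individual's spontaneous-magnitude distribution, which removes
    individual-specific scale factors (skull thickness, electrode impedance)
    shared by spontaneous and evoked activity. The package characterizes the
    rating-response relationship with global and two-piecewise linear models
    split at the pinprick-pain threshold (NRS = 4), quantifies
    inter-individual variability before and after normalization (per-level
    ANOVA F, threshold and regression-parameter variances), and implements a
    two-stage leave-one-individual-out predictor: linear-discriminant
    classification of low- versus high-pain trials followed by linear
    regression of ratings for high-pain trials. A seeded synthetic cohort
    generator emulating the study design (34 individuals, 12-15 laser energy
    levels, 10 pulses per level) makes every stage testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, signal
Suggests: testthat (>= 3.0.0), MASS, jsonlite, withr, optparse
Config/testthat/edition: 3
biocViews: Electrophysiology, Preprocessing, Normalization, Classification,
    Regression
RoxygenNote: 7.3.3
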