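Package: painstack
Title: Two-Stage Video Pain Recognition with Grayscale Short-Term Stacking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-based recognition of acute pain in laboratory animal video.
    Implements the full two-stage pipeline: one-frame-per-second sampling,
    subject detection and cropping, Grayscale Short-Term Stacking (GrayST) of
    three consecutive grayscale frames into the colour channels, image
    embedding with a deterministic pixel-statistics backend, a from-scratch
    Gaussian naive Bayes classifier, confidence-ranked Top-N frame selection
    with retraining on the selected frames, frame-to-video aggregation by
    average pooling, and leave-one-subject-out cross-validation. Ships a
    seeded synthetic-video generator (moving textured subject, cage-bar
    occlusion, motion blur, absent frames) so the whole pipeline is testable
    without animal footage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'detect.R'
    'evaluation.R'
    'grayst.R'
    'modeling.R'
    'painstack-package.R'
    'pipeline.R'
    'presets.R'
    'synthetic.R'
    'utils.R'
    'video_io.R'
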