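Package: PostureIPA
Title: Depth-Camera Posture Features and a Summary Index for Postural
    Abnormalities in Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies standing posture from depth-camera body landmarks.
    Reads landmark or Kinect-v2 skeleton recordings, extracts six kinematic
    posture features (lateral head and trunk flexion on the coronal plane;
    forward head flexion, total and waist-level trunk flexion, and a
    normalized spine-convexity ratio on the sagittal plane), combines them
    into a weighted summary index for postural abnormalities (IPA), and
    classifies subjects against published screening cut-offs. Includes a
    cohort-statistics layer (normality-gated group comparisons, Spearman
    correlation with interpretation bands, simple linear regression, ROC
    analysis with Youden-optimal cut-offs and DeLong confidence intervals)
    and a synthetic-data generator that builds geometric skeletons realizing
    prescribed posture angles and simulates cohorts from published group
    feature distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    nortest,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'landmarks-io.R'
    'features.R'
    'ipa.R'
    'cohort-stats.R'
    'roc.R'
    'synthetic.R'
    'cli.R'
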