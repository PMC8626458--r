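Package: fallsense
Title: Subject-Aware Evaluation of Wearable Fall-Detection Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how the physical characteristics of
    experimental subjects (weight, height, body-mass index, age, sex) and
    the typology of the training activities affect accelerometer-based
    wearable fall-detection classifiers. Provides a CSV manifest data
    model for tri-axial accelerometer trials, a synthetic dataset
    generator with category-specific waveform kernels, peak-centred
    2-second windowing with twelve accelerometry features, a
    thirty-variant supervised classifier grid (support vector machines,
    k-nearest neighbours, naive Bayes, decision trees), five train/test
    partition protocols including subject-wise, characteristic-sorted and
    activity-category holdout splits, and sensitivity/specificity/
    geometric-mean evaluation with fold aggregation and a
    "not computable" sentinel.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
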