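Package: rpvaudit
Title: Mislabel Detection in Digitised Specimen Collections via
    Reoccurring Prediction Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An image-classification audit pipeline for finding mislabelled
    specimens in digitised natural history collections. The pipeline
    repeatedly retrains a classifier on fresh random train/validation
    subsets of a specimen catalog, runs inference on the remaining images,
    and aggregates consistent mispredictions into a per-specimen
    Reoccurring Prediction Value (RPV): the number of runs in which the
    classifier assigned the same species label that differs from the
    specimen's current catalog label. Includes detection-based cropping,
    training-set augmentation, an attention quality-control metric,
    interval reporting of RPVs, expert-verification triage utilities, and
    a synthetic specimen-image generator with controlled label-noise
    injection so the whole method can be exercised and validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
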