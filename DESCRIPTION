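Package: beeNose
Title: Electronic-Nose Classification of Honeybee Worker Biological Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, feature extraction and classification pipeline for
    six-sensor metal-oxide (TGS) electronic-nose recordings of honeybee worker
    samples. Generates seeded synthetic exposure/regeneration time series with
    class-dependent plateaus, device offsets and chamber-insert shifts; reduces
    each recording to a six-descriptor feature vector at a fixed reference
    second with optional baseline differential correction; computes per-class
    scent signatures (squared normalized mean sensor intensities); implements
    ten classifiers (1-nearest-neighbour and inverse-distance weighted voting
    under Canberra, Euclidean, Manhattan and max-min-normalized metrics, plus
    two epsilon-indiscernibility Naive Bayes variants); and evaluates them by
    stratified Monte Carlo cross-validation with balanced accuracy, per-class
    accuracy and true positive rate, over device/insert/baseline-correction
    options and one-vs-rest variants.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    class,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'io.R'
    'features.R'
    'signatures.R'
    'classifiers.R'
    'evaluate.R'
    'sweep.R'
    'pipeline.R'
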