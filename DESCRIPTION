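Package: normgradiqa
Title: Consistent and Explainable No-Reference Image Quality Assessment
    with NormGrad Saliency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gradient-based saliency mapping for localized medical image
    quality defects. Implements NormGrad saliency with the three virtual
    identity layer variants (scaling, 1x1 and NxN convolution), multi-layer
    aggregation by pixelwise geometric mean, and the standard comparison
    detectors (Input x Gradient, Guided Backpropagation, Grad-CAM, Guided
    Grad-CAM). Ships a self-contained instrumented CNN engine with named
    capture layers, He-initialised randomisation schemes and momentum-SGD
    training, a synthetic generator for chest-X-ray-like foreign-object and
    cardiac-MR-like outflow-tract defect benchmarks with bounding-box
    annotations, and the quantitative evaluation machinery: Gaussian map
    smoothing, the Pointing Game localization metric with tolerance tau,
    repeated-trial aggregation, and the Difference-of-Means consistency
    score (linear-kernel MMD in one dimension).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, png, yaml, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'nn-engine.R'
    'classifier.R'
    'normgrad.R'
    'baselines.R'
    'evaluation.R'
    'synthetic-data.R'
    'train.R'
    'io.R'
    'experiment.R'
    'cli.R'
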