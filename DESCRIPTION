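Package: cxrnet
Title: Chest Radiograph Abnormality Classification with Attention CNNs
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for five-class chest
    radiograph abnormality classification (No Finding, Cardiomegaly,
    Effusion, Pneumothorax, Pneumonia). Provides a synthetic radiograph
    phantom generator with ground-truth lesion coordinates, three-channel
    image preprocessing (z-score normalisation, histogram equalisation with
    Gaussian smoothing, and intensity-threshold diaphragm removal),
    class-balancing augmentation planning and execution, three
    convolutional backbones (ResNet-style bottleneck, grouped-convolution
    ResNeXt, and a feature-selective/spatial-receptive-field attention
    block) with a from-scratch training engine (Adam, early stopping,
    cross-validation), Grad-CAM saliency maps, multi-class evaluation
    metrics with one-vs-rest ROC/AUC, and template-based clinical report
    generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'cxrnet-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'augment.R'
    'nn-layers.R'
    'nn-blocks.R'
    'nn-network.R'
    'gradcam.R'
    'phantom.R'
    'preprocess.R'
    'report.R'
    'train.R'
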