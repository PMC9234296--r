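Package: uscad
Title: Computer-Aided Diagnosis of Breast Ultrasound Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computer-aided diagnosis pipeline for classifying
    breast-ultrasound lesions as benign or malignant. Images are contrast
    enhanced with a sigmoid intensity mapping and despeckled by an
    interference-based median/maximum sequence followed by anisotropic
    diffusion; lesions are segmented by a deterministic hybrid of k-means and
    fuzzy c-means clustering refined with a Chan-Vese level-set contour;
    morphological, grey-level co-occurrence and first-order features are fused
    and reduced by principal component analysis; classification uses a wavelet
    neural network with Haar activations trained by Levenberg-Marquardt, with
    hyperparameters tuned by grey wolf optimization. A seeded speckled-phantom
    generator provides ground-truth test data so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
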