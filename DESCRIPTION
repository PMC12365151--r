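Package: cmmfnet
Title: Multimodal Contrastive Fusion Network for Lung Adenocarcinoma Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies lung adenocarcinoma subtypes (AIS, MIA, IA) from 3D CT
    lesions and clinical records. Implements a dual-scale vision-transformer CT
    encoder conditioned on lesion bounding boxes, a fully connected clinical
    encoder, CLIP-style contrastive alignment of image and clinical features,
    a two-phase attention fusion module (multi-head self-attention followed by
    channel attention), and a dynamically weighted contrastive-plus-focal
    training objective. Includes isotropic resampling, Hounsfield-unit
    windowing, dual-scale lesion-centred cropping with relative bounding-box
    coordinates, stratified five-fold cross-validated training with macro
    metrics and one-vs-rest AUC, and a class-conditional synthetic lesion
    phantom generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
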