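Package: vfssvit
Title: Vision Transformer Classification of Videofluoroscopic Swallowing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated detection of airway invasion in videofluoroscopic
    swallowing studies (VFSS). Implements a standardized fluoroscopy video
    cleaning pipeline (patient-information band cropping by horizontal Prewitt
    response, circular targeting-artifact removal by Hough detection and
    harmonic inpainting, resolution unification, circular field-of-view
    masking, bilateral denoising and contrast-limited adaptive histogram
    equalization), a vision transformer over 3D spatio-temporal patches with a
    class token, learnable positional embeddings and a sigmoid head, trained
    with Adam under binary cross-entropy with subject-level data splits,
    augmentation and early stopping, plus attention-rollout saliency maps
    overlaid on a quiescent frame. A synthetic fluoroscopy phantom generator
    with a planted airway-invasion signature makes the full pipeline trainable
    and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    tiff,
    png,
    EBImage,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
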