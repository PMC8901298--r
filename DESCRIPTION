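Package: glhosvd
Title: Two-Stage Higher-Order SVD Denoising for Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Denoises multi-direction diffusion-weighted MR image stacks with a
    two-stage higher-order singular value decomposition (HOSVD) scheme: a global
    HOSVD hard-threshold prefilter of the whole slice stack followed by a
    prefilter-guided local block-matching HOSVD with weighted aggregation
    (GL-HOSVD). Includes synthetic diffusion-tensor phantoms with Rician noise,
    quality metrics (PSNR, FA root-mean-square error), DTI fitting, ADC maps,
    stroke phantoms with infarct-core/penumbra contrast, and diagnostic
    concordance statistics (sensitivity, specificity, accuracy, Cohen's kappa)
    for penumbra detection studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
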