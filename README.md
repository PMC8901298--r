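# glhosvd

Two-stage higher-order SVD (GL-HOSVD) denoising for multi-direction
diffusion-weighted MRI, with the evaluation stack that typically accompanies
a DWI denoising study: synthetic diffusion-tensor phantoms with Rician noise,
PSNR and FA-RMSE quality metrics, DTI and two-point ADC map estimation,
stroke phantoms with infarct-core/penumbra contrast, and 2 x 2 diagnostic
concordance statistics (sensitivity, specificity, accuracy, Cohen's kappa).

## Who this is for

DWI images are acquired once per diffusion direction at low SNR, which blurs
the apparent-diffusion-coefficient (ADC) contrast that radiologists use to
delineate the ischemic penumbra in early stroke. Because all Q directional
images show the same anatomy, the H x W x Q stack is a highly redundant
third-order tensor. This package is for people who want a reproducible,
scriptable implementation of guided tensor denoising on such stacks — and for
anyone who needs the surrounding bookkeeping (phantoms, quality metrics,
diagnostic tables) in one place.

## The method

1. **Global prefilter.** Decompose the whole H x W x Q stack by full HOSVD
   (orthonormal factors from the SVD of each mode unfolding), hard-threshold
   the core at the universal threshold
   `tau = q_global * sigma * sqrt(2 ln(HWQ))`, reconstruct, clamp at zero.
2. **Guided local stage.** Slide m x m x Q reference blocks over the image;
   group each with its nearest blocks (mean-squared distance measured on the
   *prefiltered* image, threshold `tau_d`, at most `L_max` blocks); compute
   the order-4 HOSVD basis from the prefiltered group; project the *noisy*
   group onto it; hard-threshold at
   `q_local * sigma * sqrt(2 ln(m^2 Q L))`; reconstruct; aggregate all
   overlapping pixel estimates with weights `theta = 1 / (1 + ||core||_0)`.

The result is deterministic given the input and configuration. See the
methods vignette (`vignettes/gl-hosvd-methods.Rmd`) for assumptions,
parameter guidance and design notes.

## Worked example

```r
library(glhosvd)

ph    <- simulate_dwi(phantom_spec())              # noise-free 64 x 64 x 13 phantom
noisy <- add_rician_noise(ph$stack, 0.05, seed = 1)
fit   <- gl_hosvd(noisy, denoise_config(sigma = 0.05))
summary(fit, reference = ph$stack)
#> GL-HOSVD: sigma = 0.05, tau_global = 0.23327, residual sd = 0.050675
#> PSNR (dB):
#>       noisy prefiltered    denoised
#>       25.98       35.84       39.81
```

The three PSNR values say: the Rician-corrupted stack sits at 26 dB against
the noise-free truth; the global HOSVD prefilter alone recovers ~10 dB; the
guided local stage adds ~4 dB more. The same ordering holds for the FA error
of the fitted diffusion tensors (`fa_rmse`, see the vignette).

Diagnostic tables work standalone:

```r
tab <- confusion_table(tp = 52, fp = 7, fn = 38, tn = 8)
sen_spec_acc(tab)
#> diagnostic performance (%):
#> sensitivity specificity    accuracy
#>       57.78       53.33       57.14
cohen_kappa(tab)
#> Cohen's kappa = 0.0597 (p_o = 0.5714, p_e = 0.5442): not ideal
```

A thin command-line interface wraps the same functions
(`inst/cli/glhosvd.R`): subcommands `phantom`, `denoise`, `metrics`, `adc`
and `diagnose`, e.g.

```sh
Rscript inst/cli/glhosvd.R diagnose --table 52,7,38,8
Rscript inst/cli/glhosvd.R denoise --input dwi.nii.gz --bvals f.bval \
    --bvecs f.bvec --sigma 0.05 --output denoised.nii.gz
```

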