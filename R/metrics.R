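#' Peak signal-to-noise ratio (peak-1 convention)
#'
#' `PSNR = 10 * log10(M / SSE)` where M is the pixel count and SSE the summed
#' squared difference, i.e. `-10 * log10(MSE)` on images normalized so the
#' noise-free peak is 1. Strictly decreasing in elementwise error; `Inf` (with
#' a warning) for identical images.
#'
#' @param reference noise-free [dwi_stack()] or numeric array (peak-1 scale).
#' @param estimate same-shape [dwi_stack()] or array.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, estimate) {
  ref <- as_intensities(reference)
  est <- as_intensities(estimate)
  if (!identical(dims_of(ref), dims_of(est)))
    stop("images must share a shape", call. = FALSE)
  sse <- sum((ref - est)^2)
  if (sse == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(length(ref) / sse)
}

#' Root-mean-square error between two FA maps
#'
#' `sqrt(sum((a - b)^2) / M)` over the M pixels. With `squared = TRUE` the
#' mean squared error (no root) is returned instead.
#'
#' @param ref_fa,est_fa numeric matrices of the same shape.
#' @param squared return the squared (MSE) variant.
#' @return nonnegative scalar; zero iff the maps are identical.
#' @export
fa_rmse <- function(ref_fa, est_fa, squared = FALSE) {
  if (!identical(dims_of(ref_fa), dims_of(est_fa)))
    stop("FA maps must share a shape", call. = FALSE)
  mse <- sum((ref_fa - est_fa)^2) / length(ref_fa)
  if (squared) mse else sqrt(mse)
}

#' Fractional anisotropy from diffusion-tensor eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`; 0 for the zero
#' tensor and for isotropic tensors.
#'
#' @param ev numeric vector of 3 eigenvalues (clamped at 0 internally).
#' @return FA in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(ev) {
  ev <- pmax(ev, 0)
  nrm <- sqrt(sum(ev^2))
  if (nrm == 0) return(0)
  min(1, sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / nrm)
}

#' Pixelwise diffusion-tensor fit (log-linear least squares)
#'
#' Ordinary least squares of log-signals on the six unique tensor components
#' (plus an intercept for log S0) at every pixel with all-positive signals:
#' `log S = log s0 - b * t(g) %*% D %*% g`. Eigenvalues are clamped at zero
#' before FA. Pixels with any nonpositive signal are masked (NA).
#'
#' @param stack a [dwi_stack()] with at least 7 volumes including one b = 0.
#' @param weighted use weighted least squares with weights S^2 (the
#'   first-order variance correction for log-transformed signals).
#' @return object of class `dti_field`: list with `tensors` (H x W x 6 array,
#'   order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, mm^2/s), `eigenvalues` (H x W x 3,
#'   decreasing), `fa`, `md` (mean diffusivity), `s0`, `mask`.
#' @export
fit_dti <- function(stack, weighted = FALSE) {
  stopifnot(inherits(stack, "dwi_stack"))
  if (stack$Q < 7L || !any(stack$bvals == 0))
    stop("DTI fit needs >= 7 volumes including one b = 0", call. = FALSE)
  g <- stack$bvecs
  design <- cbind(1, -stack$bvals * t(rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
                                            2 * g[1, ] * g[2, ],
                                            2 * g[1, ] * g[3, ],
                                            2 * g[2, ] * g[3, ])))
  H <- stack$H; W <- stack$W
  sig <- matrix(stack$intensities, H * W, stack$Q)
  ok <- rowSums(sig <= 0) == 0L
  coefs <- matrix(NA_real_, H * W, 7L)
  if (any(ok)) {
    if (weighted) {
      # per-pixel weights: solve each masked pixel separately
      idx <- which(ok)
      for (p in idx) {
        w <- sig[p, ]^2
        coefs[p, ] <- stats::lm.wfit(design, log(sig[p, ]), w)$coefficients
      }
    } else {
      # one shared design: normal equations solved once for all pixels
      qr_d <- qr(design)
      coefs[ok, ] <- t(qr.coef(qr_d, t(log(sig[ok, , drop = FALSE]))))
    }
  }
  ev <- matrix(NA_real_, H * W, 3L)
  fa <- md <- rep(NA_real_, H * W)
  for (p in which(ok)) {
    D <- matrix(c(coefs[p, 2], coefs[p, 5], coefs[p, 6],
                  coefs[p, 5], coefs[p, 3], coefs[p, 7],
                  coefs[p, 6], coefs[p, 7], coefs[p, 4]), 3, 3)
    lam <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    ev[p, ] <- lam
    lamc <- pmax(lam, 0)
    fa[p] <- fa_from_eigenvalues(lamc)
    md[p] <- mean(lamc)
  }
  structure(list(tensors = array(coefs[, 2:7], c(H, W, 6L)),
                 eigenvalues = array(ev, c(H, W, 3L)),
                 fa = matrix(fa, H, W), md = matrix(md, H, W),
                 s0 = matrix(exp(coefs[, 1]), H, W),
                 mask = matrix(ok, H, W)),
            class = "dti_field")
}

#' @export
print.dti_field <- function(x, ...) {
  cat(sprintf("DTI field: %d x %d pixels, %d fitted (%.1f%%)\n",
              nrow(x$fa), ncol(x$fa), sum(x$mask),
              100 * mean(x$mask)))
  cat(sprintf("FA range [%.3f, %.3f], MD range [%.3g, %.3g] mm^2/s\n",
              min(x$fa, na.rm = TRUE), max(x$fa, na.rm = TRUE),
              min(x$md, na.rm = TRUE), max(x$md, na.rm = TRUE)))
  invisible(x)
}

#' Two-point apparent diffusion coefficient map
#'
#' Mono-exponential two-point ADC: `ADC = ln(S_low / S_high) / (b_high -
#' b_low)` per pixel, positive where the signal decays with b. Pixels with a
#' nonpositive signal in either volume are masked (NA).
#'
#' @param stack a [dwi_stack()].
#' @param b_low_index,b_high_index volume indices of the low- and high-b
#'   images; `b_high > b_low` required.
#' @return object of class `adc_map`: list with `adc` (H x W, mm^2/s),
#'   `b_low`, `b_high`, `mask`.
#' @export
adc_map <- function(stack, b_low_index = which.min(stack$bvals),
                    b_high_index = which.max(stack$bvals)) {
  stopifnot(inherits(stack, "dwi_stack"))
  b1 <- stack$bvals[b_low_index]; bn <- stack$bvals[b_high_index]
  if (!(bn > b1)) stop("`b_high` must exceed `b_low`", call. = FALSE)
  s1 <- stack$intensities[, , b_low_index]
  sn <- stack$intensities[, , b_high_index]
  ok <- s1 > 0 & sn > 0
  adc <- matrix(NA_real_, stack$H, stack$W)
  adc[ok] <- log(s1[ok] / sn[ok]) / (bn - b1)
  structure(list(adc = adc, b_low = b1, b_high = bn, mask = ok),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("ADC map (b = %g vs %g s/mm^2): range [%.3g, %.3g] mm^2/s, %d masked\n",
              x$b_low, x$b_high, min(x$adc, na.rm = TRUE),
              max(x$adc, na.rm = TRUE), sum(!x$mask)))
  invisible(x)
}

#' Denoising quality report
#'
#' PSNR against a noise-free reference and, when ground-truth FA is supplied,
#' FA-RMSE of the DTI fit of the estimate.
#'
#' @param reference noise-free [dwi_stack()].
#' @param estimate denoised or noisy [dwi_stack()].
#' @param ref_fa optional ground-truth FA matrix; triggers a DTI fit of
#'   `estimate`.
#' @return list with `psnr_db`, `m_pixels` and, if `ref_fa` given, `fa_rmse`
#'   and `m_fa_pixels`.
#' @export
quality_report <- function(reference, estimate, ref_fa = NULL) {
  out <- list(psnr_db = psnr(reference, estimate),
              m_pixels = length(as_intensities(reference)))
  if (!is.null(ref_fa)) {
    fit <- fit_dti(estimate)
    est_fa <- fit$fa
    est_fa[!fit$mask] <- 0
    out$fa_rmse <- fa_rmse(ref_fa, est_fa)
    out$m_fa_pixels <- length(ref_fa)
  }
  out
}

as_intensities <- function(x) {
  if (inherits(x, "dwi_stack")) x$intensities else x
}
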