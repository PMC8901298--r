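#' Construct a diffusion-weighted image stack
#'
#' Bundles an H x W x Q array of magnitude DWI slices (one 2-D slice per
#' diffusion-encoding volume) with its gradient table. Intensities are
#' magnitude data and must be nonnegative; by convention images are scaled so
#' the noise-free peak is 1.
#'
#' @param intensities numeric array H x W x Q (a matrix is treated as Q = 1).
#' @param bvals numeric vector of Q b-values (s/mm^2).
#' @param bvecs 3 x Q numeric matrix of unit gradient directions; columns for
#'   b = 0 volumes must be zero vectors.
#' @return an object of class `dwi_stack`: list with `intensities`, `bvals`,
#'   `bvecs` and dimensions `H`, `W`, `Q`.
#' @examples
#' s <- dwi_stack(array(runif(8 * 8 * 2), c(8, 8, 2)), bvals = c(0, 1000),
#'                bvecs = cbind(c(0, 0, 0), c(1, 0, 0)))
#' s$Q
#' @export
dwi_stack <- function(intensities, bvals, bvecs) {
  if (is.matrix(intensities)) dim(intensities) <- c(dim(intensities), 1L)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be an H x W x Q array", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("`intensities` contains non-finite values", call. = FALSE)
  if (any(intensities < 0))
    stop("magnitude intensities must be nonnegative", call. = FALSE)
  d <- dim(intensities)
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("`bvecs` must be a 3 x Q matrix (FSL dialect)", call. = FALSE)
  if (length(bvals) != d[3L] || ncol(bvecs) != d[3L])
    stop("gradient table length (", length(bvals), ", ", ncol(bvecs),
         ") does not match volume count Q = ", d[3L], call. = FALSE)
  nrm <- sqrt(colSums(bvecs^2))
  nz <- nrm > 0
  if (any(abs(nrm[nz] - 1) > 1e-6))
    stop("nonzero gradient directions must be unit vectors", call. = FALSE)
  structure(list(intensities = intensities, bvals = bvals, bvecs = bvecs,
                 H = d[1L], W = d[2L], Q = d[3L]),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat(sprintf("DWI stack: %d x %d pixels, %d volumes (%d b=0, b in [%g, %g] s/mm^2)\n",
              x$H, x$W, x$Q, nb0, min(x$bvals), max(x$bvals)))
  cat(sprintf("intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# replace the intensity array, revalidating shape
with_intensities <- function(stack, intensities) {
  dwi_stack(intensities, stack$bvals, stack$bvecs)
}

#' Estimate the noise standard deviation of a DWI stack
#'
#' Convenience estimator (an extension beyond the core algorithm, which takes
#' sigma as a known input): robust MAD of the half-scaled horizontal first
#' differences of the first b = 0 volume. First differences of i.i.d. noise
#' have variance 2 sigma^2, so the MAD of `diff/sqrt(2)` estimates sigma where
#' the underlying image is locally smooth.
#'
#' @param stack a [dwi_stack()].
#' @return estimated noise standard deviation (intensity units of the stack).
#' @export
estimate_sigma <- function(stack) {
  stopifnot(inherits(stack, "dwi_stack"))
  q0 <- which(stack$bvals == 0)[1L]
  if (is.na(q0)) q0 <- 1L
  img <- stack$intensities[, , q0]
  d <- diff(t(img)) / sqrt(2)
  stats::mad(as.numeric(d), center = 0)
}
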