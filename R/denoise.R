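#' Configuration for GL-HOSVD denoising
#'
#' Collects the tunable parameters of the two-stage denoiser. The noise level
#' `sigma` is treated as known (on the normalized intensity scale where the
#' noise-free peak is 1); [estimate_sigma()] offers a convenience estimate.
#'
#' @param sigma noise standard deviation, >= 0.
#' @param q_global smoothness scalar for the global-stage universal threshold.
#' @param q_local smoothness scalar for the local (block-group) threshold.
#' @param m spatial block edge in pixels (blocks are m x m x Q).
#' @param search_radius half-width of the square search window around each
#'   reference block, in pixels.
#' @param tau_d block-distance threshold; default `4 * sigma^2`, scaling the
#'   acceptance band with the noise variance.
#' @param l_max maximum number of similar blocks per group.
#' @param n_step sliding step between reference blocks, `1 <= n_step <= m`.
#' @return object of class `denoise_config`.
#' @export
denoise_config <- function(sigma, q_global = 1.0, q_local = 2.2, m = 4L,
                           search_radius = 8L, tau_d = NULL, l_max = 16L,
                           n_step = 2L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("`sigma` must be a single nonnegative number", call. = FALSE)
  if (is.null(tau_d)) tau_d <- 4 * sigma^2
  m <- as.integer(m); search_radius <- as.integer(search_radius)
  l_max <- as.integer(l_max); n_step <- as.integer(n_step)
  if (q_global <= 0 || q_local <= 0) stop("q scalars must be > 0", call. = FALSE)
  if (m < 2L) stop("`m` must be >= 2", call. = FALSE)
  if (n_step < 1L || n_step > m)
    stop("`n_step` must satisfy 1 <= n_step <= m", call. = FALSE)
  if (l_max < 1L) stop("`l_max` must be >= 1", call. = FALSE)
  if (tau_d < 0) stop("`tau_d` must be >= 0", call. = FALSE)
  if (search_radius < 0) stop("`search_radius` must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, q_global = q_global, q_local = q_local,
                 m = m, search_radius = search_radius, tau_d = tau_d,
                 l_max = l_max, n_step = n_step),
            class = "denoise_config")
}

#' Universal hard threshold
#'
#' `q * sigma * sqrt(2 * ln(n_coeff))`: the noise-floor cutoff for transform
#' coefficients of `n_coeff` i.i.d. Gaussian variates of standard deviation
#' `sigma`, scaled by the smoothness factor `q`. Natural logarithm.
#'
#' @param sigma noise standard deviation, >= 0.
#' @param n_coeff number of coefficients, >= 1.
#' @param q positive smoothness scalar.
#' @return scalar threshold.
#' @export
universal_threshold <- function(sigma, n_coeff, q = 1.0) {
  if (!is.numeric(n_coeff) || length(n_coeff) != 1L || n_coeff < 1)
    stop("`n_coeff` must be a positive integer", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (q <= 0) stop("`q` must be > 0", call. = FALSE)
  q * sigma * sqrt(2 * log(n_coeff))
}

#' Global HOSVD prefilter
#'
#' First stage of GL-HOSVD: the whole H x W x Q stack is treated as one
#' third-order tensor, decomposed by HOSVD, its core hard-thresholded at the
#' universal threshold for H*W*Q coefficients, and reconstructed. Negative
#' reconstructed intensities are clamped to zero (magnitude data).
#'
#' @param noisy a [dwi_stack()].
#' @param cfg a [denoise_config()].
#' @return denoised [dwi_stack()], with the threshold used in attribute `tau`.
#' @export
global_stage <- function(noisy, cfg) {
  stopifnot(inherits(noisy, "dwi_stack"), inherits(cfg, "denoise_config"))
  f <- hosvd(noisy$intensities)
  tau <- universal_threshold(cfg$sigma, noisy$H * noisy$W * noisy$Q,
                             cfg$q_global)
  f$core <- hard_threshold(f$core, tau)
  out <- with_intensities(noisy, pmax(inverse_hosvd(f), 0))
  attr(out, "tau") <- tau
  out
}

#' Normalized squared distance between two image blocks
#'
#' `||a - b||_2^2 / n`, where n is the number of elements in a block — the
#' mean squared intensity difference. Symmetric and zero iff the blocks are
#' identical.
#'
#' @param a,b numeric arrays of identical shape (m x m x Q blocks).
#' @return nonnegative scalar.
#' @export
block_distance <- function(a, b) {
  if (!identical(dims_of(a), dims_of(b)))
    stop("blocks must have identical shapes", call. = FALSE)
  sum((a - b)^2) / length(a)
}

#' Find blocks similar to a reference block
#'
#' Scans every candidate block whose top-left corner lies within the square
#' search window of half-width `cfg$search_radius` around `ref_coord`
#' (clipped so blocks stay inside the image), computes [block_distance()] on
#' the guide image, and keeps candidates with distance <= `cfg$tau_d`.
#' Matches are sorted by ascending distance with raster-order tie-breaking;
#' the reference block is always first; at most `cfg$l_max` are returned.
#'
#' @param guide a [dwi_stack()] (typically the global-stage output).
#' @param ref_coord length-2 integer vector, 1-based top-left (row, col) of
#'   the reference block.
#' @param cfg a [denoise_config()].
#' @return list with `coords` (L x 2 matrix of 1-based corners, reference
#'   first), `ref_coord`, and `L`.
#' @export
find_similar_blocks <- function(guide, ref_coord, cfg) {
  stopifnot(inherits(guide, "dwi_stack"), inherits(cfg, "denoise_config"))
  ref_coord <- as.integer(ref_coord)
  if (length(ref_coord) != 2L ||
      ref_coord[1L] < 1L || ref_coord[2L] < 1L ||
      ref_coord[1L] + cfg$m - 1L > guide$H ||
      ref_coord[2L] + cfg$m - 1L > guide$W)
    stop("reference block does not lie fully inside the image", call. = FALSE)
  coords <- .match_blocks_cpp(as.numeric(guide$intensities),
                              guide$H, guide$W, guide$Q,
                              ref_coord[1L], ref_coord[2L],
                              cfg$m, cfg$search_radius, cfg$tau_d, cfg$l_max)
  list(coords = coords, ref_coord = ref_coord, L = nrow(coords))
}

#' Group image blocks into a fourth-order tensor
#'
#' Stacks the m x m x Q blocks at the given corners along a fourth mode.
#'
#' @param stack a [dwi_stack()].
#' @param coords L x 2 matrix of 1-based top-left corners.
#' @param m block edge in pixels.
#' @return numeric array m x m x Q x L.
#' @export
extract_group <- function(stack, coords, m) {
  stopifnot(inherits(stack, "dwi_stack"))
  coords <- as.matrix(coords)
  L <- nrow(coords)
  g <- array(0, c(m, m, stack$Q, L))
  for (l in seq_len(L)) {
    i <- coords[l, 1L]; j <- coords[l, 2L]
    g[, , , l] <- stack$intensities[i:(i + m - 1L), j:(j + m - 1L), ]
  }
  g
}

#' Denoise one similar-block group on a guided HOSVD basis
#'
#' Computes the order-4 HOSVD basis from the guide group (the prefiltered
#' blocks), projects the noisy group onto that basis, hard-thresholds the
#' projected core at the universal threshold for `m*m*Q*L` coefficients with
#' scalar `q_local`, and reconstructs. The l0 norm (nonzero count) of the
#' thresholded core is returned for the aggregation weight.
#'
#' @param noisy_group,guide_group numeric arrays m x m x Q x L (same shape).
#' @param cfg a [denoise_config()].
#' @return list with `denoised` (array m x m x Q x L), `l0` (nonzero count of
#'   the thresholded core) and `weight` (`1 / (1 + l0)`).
#' @export
denoise_group <- function(noisy_group, guide_group, cfg) {
  stopifnot(inherits(cfg, "denoise_config"))
  dn <- dims_of(noisy_group)
  if (!identical(dn, dims_of(guide_group)))
    stop("noisy and guide groups must share a shape", call. = FALSE)
  if (length(dn) != 4L || any(dn < 1L))
    stop("groups must be nonempty order-4 arrays", call. = FALSE)
  basis <- hosvd(guide_group)$factors
  s_n <- noisy_group
  for (n in 1:4) s_n <- mode_product(s_n, t(basis[[n]]), n)
  tau <- universal_threshold(cfg$sigma, prod(dn), cfg$q_local)
  s_n <- hard_threshold(s_n, tau)
  l0 <- sum(s_n != 0)
  den <- s_n
  for (n in 1:4) den <- mode_product(den, basis[[n]], n)
  list(denoised = den, l0 = l0, weight = 1 / (1 + l0))
}

#' Local guided block-matching HOSVD stage
#'
#' Second stage of GL-HOSVD. Reference blocks slide over the image with step
#' `cfg$n_step` (the last valid row/column of positions is always included so
#' every pixel is covered). For each reference block, similar blocks are
#' located on the guide image, the noisy group is denoised on the guide
#' group's HOSVD basis, and every denoised pixel estimate is accumulated with
#' weight `1 / (1 + l0)` where l0 is the group's thresholded-core nonzero
#' count. The output is the weighted mean per pixel, clamped at zero.
#'
#' @param noisy a [dwi_stack()] (the original noisy data).
#' @param guide a [dwi_stack()] of the same shape (the prefiltered image).
#' @param cfg a [denoise_config()].
#' @return denoised [dwi_stack()].
#' @export
local_stage <- function(noisy, guide, cfg) {
  stopifnot(inherits(noisy, "dwi_stack"), inherits(guide, "dwi_stack"),
            inherits(cfg, "denoise_config"))
  if (!identical(dim(noisy$intensities), dim(guide$intensities)))
    stop("noisy and guide stacks must share a shape", call. = FALSE)
  H <- noisy$H; W <- noisy$W; m <- cfg$m
  if (H < m || W < m)
    stop("image smaller than the block size in a spatial dimension",
         call. = FALSE)
  pos_i <- unique(c(seq.int(1L, H - m + 1L, by = cfg$n_step), H - m + 1L))
  pos_j <- unique(c(seq.int(1L, W - m + 1L, by = cfg$n_step), W - m + 1L))
  num <- array(0, dim(noisy$intensities))
  wt <- array(0, dim(noisy$intensities))
  for (i in pos_i) {
    for (j in pos_j) {
      grp <- find_similar_blocks(guide, c(i, j), cfg)
      noisy_g <- extract_group(noisy, grp$coords, m)
      guide_g <- extract_group(guide, grp$coords, m)
      est <- denoise_group(noisy_g, guide_g, cfg)
      for (l in seq_len(grp$L)) {
        ii <- grp$coords[l, 1L]:(grp$coords[l, 1L] + m - 1L)
        jj <- grp$coords[l, 2L]:(grp$coords[l, 2L] + m - 1L)
        num[ii, jj, ] <- num[ii, jj, ] + est$weight * est$denoised[, , , l]
        wt[ii, jj, ] <- wt[ii, jj, ] + est$weight
      }
    }
  }
  if (any(wt == 0)) stop("internal error: uncovered pixels after sliding pass")
  with_intensities(noisy, pmax(num / wt, 0))
}

#' Two-stage GL-HOSVD denoising
#'
#' Runs the global HOSVD prefilter and then the prefilter-guided local
#' block-matching HOSVD stage. The prefiltered image serves only as the guide
#' for block matching and basis computation; the local stage filters the
#' original noisy data. Deterministic given inputs and configuration.
#'
#' @param noisy a [dwi_stack()] of magnitude DWI slices (peak-1 scale).
#' @param cfg a [denoise_config()]; alternatively pass `sigma` and friends
#'   via `...` to build one.
#' @param ... parameters forwarded to [denoise_config()] when `cfg` is NULL.
#' @return an object of class `gl_hosvd` with components `denoised` and
#'   `prefiltered` (both [dwi_stack()]), `input`, `config`, `tau_global`, and
#'   `elapsed` (seconds). Methods: [print.gl_hosvd()], [summary.gl_hosvd()],
#'   [residuals.gl_hosvd()], [plot.gl_hosvd()].
#' @examples
#' ph <- simulate_dwi(phantom_spec(shape = c(24, 24), n_directions = 6))
#' noisy <- add_rician_noise(ph$stack, 0.05, seed = 1)
#' fit <- gl_hosvd(noisy, denoise_config(sigma = 0.05, m = 3, n_step = 3))
#' psnr(ph$stack, fit$denoised) > psnr(ph$stack, noisy)
#' @export
gl_hosvd <- function(noisy, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- denoise_config(...)
  stopifnot(inherits(noisy, "dwi_stack"), inherits(cfg, "denoise_config"))
  t0 <- proc.time()[["elapsed"]]
  pre <- global_stage(noisy, cfg)
  den <- local_stage(noisy, pre, cfg)
  structure(list(call = match.call(), config = cfg, input = noisy,
                 prefiltered = pre, denoised = den,
                 tau_global = attr(pre, "tau"),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "gl_hosvd")
}

#' @export
print.gl_hosvd <- function(x, ...) {
  cat("GL-HOSVD denoising result\n")
  cat(sprintf("  stack: %d x %d x %d; sigma = %g\n",
              x$input$H, x$input$W, x$input$Q, x$config$sigma))
  cat(sprintf("  global threshold: %.5g; block %d px, step %d, L_max %d\n",
              x$tau_global, x$config$m, x$config$n_step, x$config$l_max))
  cat(sprintf("  elapsed: %.2f s\n", x$elapsed))
  invisible(x)
}

#' Summary of a GL-HOSVD fit
#'
#' @param object a `gl_hosvd` object.
#' @param reference optional noise-free [dwi_stack()]; when supplied, PSNR of
#'   the noisy input, the prefiltered stage and the final output are reported.
#' @param ... unused.
#' @export
summary.gl_hosvd <- function(object, reference = NULL, ...) {
  res <- residuals(object)
  out <- list(config = object$config, tau_global = object$tau_global,
              residual_sd = stats::sd(res), elapsed = object$elapsed)
  if (!is.null(reference)) {
    out$psnr <- c(noisy = psnr(reference, object$input),
                  prefiltered = psnr(reference, object$prefiltered),
                  denoised = psnr(reference, object$denoised))
  }
  class(out) <- "summary.gl_hosvd"
  out
}

#' @export
print.summary.gl_hosvd <- function(x, ...) {
  cat(sprintf("GL-HOSVD: sigma = %g, tau_global = %.5g, residual sd = %.5g\n",
              x$config$sigma, x$tau_global, x$residual_sd))
  if (!is.null(x$psnr)) {
    cat("PSNR (dB):\n")
    print(round(x$psnr, 2))
  }
  invisible(x)
}

#' Residuals of a GL-HOSVD fit (noisy minus denoised)
#'
#' @param object a `gl_hosvd` object.
#' @param ... unused.
#' @return numeric array H x W x Q.
#' @export
residuals.gl_hosvd <- function(object, ...) {
  object$input$intensities - object$denoised$intensities
}

#' Plot a GL-HOSVD result (noisy vs denoised slice)
#'
#' @param x a `gl_hosvd` object.
#' @param volume which diffusion volume to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.gl_hosvd <- function(x, volume = 1L, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  zl <- range(x$input$intensities[, , volume],
              x$denoised$intensities[, , volume])
  pal <- grDevices::gray.colors(256, start = 0, end = 1)
  graphics::image(x$input$intensities[, , volume], zlim = zl, col = pal,
                  axes = FALSE, main = "noisy", ...)
  graphics::image(x$denoised$intensities[, , volume], zlim = zl, col = pal,
                  axes = FALSE, main = "denoised", ...)
  invisible(x)
}
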