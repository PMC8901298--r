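#' Mode-n matricization of a tensor
#'
#' Unfolds an order-N array along one mode. Rows are indexed by the chosen
#' mode; columns enumerate the remaining modes in increasing mode order
#' (mode indices cycle fastest for the lowest remaining mode), i.e. the
#' column-major order of the array with the chosen mode permuted to the
#' front. `fold()` is the exact inverse.
#'
#' @param tensor numeric array (any order >= 1).
#' @param mode integer mode index in `1..length(dim(tensor))`.
#' @return a matrix with `dim(tensor)[mode]` rows.
#' @seealso [fold()], [mode_product()]
#' @export
unfold <- function(tensor, mode) {
  d <- dims_of(tensor)
  check_mode(mode, length(d))
  if (length(d) == 1L) return(matrix(tensor, nrow = d, ncol = 1L))
  perm <- c(mode, seq_along(d)[-mode])
  matrix(aperm(tensor, perm), nrow = d[mode])
}

#' Fold a matricization back into a tensor
#'
#' Inverse of [unfold()]: rebuilds the array of dimensions `dims` from its
#' mode-`mode` unfolding (same column convention as [unfold()]).
#'
#' @param mat matrix as produced by [unfold()].
#' @param mode mode index the matrix was unfolded along.
#' @param dims integer vector, the target array dimensions.
#' @return numeric array with `dim == dims`.
#' @export
fold <- function(mat, mode, dims) {
  check_mode(mode, length(dims))
  if (length(mat) != prod(dims))
    stop("matrix size does not match the target dimensions", call. = FALSE)
  if (length(dims) == 1L) return(array(mat, dim = dims))
  perm <- c(mode, seq_along(dims)[-mode])
  arr <- array(mat, dim = dims[perm])
  aperm(arr, order(perm))
}

#' n-mode product of a tensor and a matrix
#'
#' Multiplies `tensor` along `mode` by `mat`: the mode-`mode` unfolding is
#' premultiplied by `mat` and folded back, so that mode's extent becomes
#' `nrow(mat)`.
#'
#' @param tensor numeric array.
#' @param mat numeric matrix with `ncol(mat) == dim(tensor)[mode]`.
#' @param mode mode index.
#' @return numeric array.
#' @export
mode_product <- function(tensor, mat, mode) {
  d <- dims_of(tensor)
  check_mode(mode, length(d))
  mat <- as.matrix(mat)
  if (ncol(mat) != d[mode])
    stop("matrix column count does not match the tensor extent along mode ",
         mode, call. = FALSE)
  d2 <- d
  d2[mode] <- nrow(mat)
  fold(mat %*% unfold(tensor, mode), mode, d2)
}

#' Higher-order singular value decomposition (Tucker/HOSVD)
#'
#' Computes the full (non-truncated) HOSVD of an order-N array: for each mode
#' the complete matrix of left singular vectors of that mode's unfolding, and
#' the all-orthogonal core obtained by projecting the tensor onto those bases.
#' No rank truncation is performed; denoising is done by thresholding the core
#' coefficients, not by dropping ranks.
#'
#' @param tensor numeric array with finite entries.
#' @return an object of class `hosvd_factors`: a list with `core` (array, same
#'   shape as `tensor`), `factors` (list of square orthonormal matrices, one
#'   per mode) and `order` (number of modes).
#' @seealso [inverse_hosvd()], [hard_threshold()]
#' @export
hosvd <- function(tensor) {
  if (!all(is.finite(tensor)))
    stop("tensor contains non-finite entries", call. = FALSE)
  d <- dims_of(tensor)
  if (is.null(dim(tensor))) dim(tensor) <- d
  factors <- vector("list", length(d))
  for (n in seq_along(d)) {
    un <- unfold(tensor, n)
    factors[[n]] <- svd(un, nu = nrow(un), nv = 0L)$u
  }
  core <- tensor
  for (n in seq_along(d)) core <- mode_product(core, t(factors[[n]]), n)
  structure(list(core = core, factors = factors, order = length(d)),
            class = "hosvd_factors")
}

#' Reconstruct a tensor from HOSVD factors
#'
#' Multiplies the core by every factor matrix in mode order. For an
#' unmodified decomposition this inverts [hosvd()] to within floating-point
#' round-off; with a thresholded core it yields the filtered tensor.
#'
#' @param f an object of class `hosvd_factors` (core may have been modified).
#' @return numeric array with the shape implied by the factors.
#' @export
inverse_hosvd <- function(f) {
  if (!inherits(f, "hosvd_factors"))
    stop("`f` must be a hosvd_factors object", call. = FALSE)
  d <- dims_of(f$core)
  if (length(f$factors) != length(d))
    stop("number of factors does not match core order", call. = FALSE)
  out <- f$core
  for (n in seq_along(d)) {
    fac <- f$factors[[n]]
    if (ncol(fac) != d[n])
      stop("factor ", n, " is incompatible with the core shape", call. = FALSE)
    out <- mode_product(out, fac, n)
  }
  out
}

#' Hard-threshold transform coefficients
#'
#' Zeroes every coefficient with `abs(s) < tau`; coefficients with
#' `abs(s) >= tau` are kept unchanged (ties at the threshold are kept).
#'
#' @param core numeric array of transform coefficients.
#' @param tau nonnegative scalar threshold.
#' @return array of the same shape with small coefficients zeroed.
#' @export
hard_threshold <- function(core, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("`tau` must be a single nonnegative number", call. = FALSE)
  core * (abs(core) >= tau)
}

## internal helpers -----------------------------------------------------------

dims_of <- function(x) {
  if (length(x) < 1L) stop("tensor has no elements", call. = FALSE)
  d <- dim(x)
  if (is.null(d)) length(x) else d
}

check_mode <- function(mode, order) {
  if (!is.numeric(mode) || length(mode) != 1L || is.na(mode) ||
      mode != as.integer(mode) || mode < 1L || mode > order)
    stop("invalid mode index: ", mode, call. = FALSE)
  invisible(TRUE)
}
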