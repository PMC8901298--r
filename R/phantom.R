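#' Specification of a synthetic diffusion-tensor phantom
#'
#' Describes a 2-D piecewise diffusion-tensor field from which multi-direction
#' DWI signals are simulated. The default geometry is three concentric
#' regions: an isotropic background, a strongly anisotropic annulus, and an
#' anisotropic inner disk with a different principal axis, giving the phantom
#' both FA contrast and directional structure.
#'
#' @param shape length-2 integer vector, image height and width in pixels.
#' @param n_directions number of diffusion-encoding directions Q (>= 6 for a
#'   DTI-fittable phantom); one b = 0 volume is always added.
#' @param bval diffusion sensitization in s/mm^2.
#' @param s0 baseline (b = 0) signal; images are on the peak-1 scale.
#' @param region_map integer matrix of region labels (default: concentric
#'   disks built from `shape`).
#' @param region_tensors named list mapping label -> symmetric positive
#'   semi-definite 3 x 3 diffusion tensor in mm^2/s.
#' @param noise_level Rician noise level relative to peak intensity, in
#'   `[0, 0.1]`.
#' @param seed integer seed for noise realizations.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L), n_directions = 12L, bval = 1000,
                         s0 = 1, region_map = NULL, region_tensors = NULL,
                         noise_level = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers", call. = FALSE)
  if (noise_level < 0 || noise_level > 0.1)
    stop("`noise_level` must lie in [0, 0.1]", call. = FALSE)
  if (n_directions < 1L)
    stop("`n_directions` must be >= 1", call. = FALSE)
  if (is.null(region_map)) region_map <- concentric_region_map(shape)
  if (is.null(region_tensors)) region_tensors <- default_region_tensors()
  labs <- sort(unique(as.integer(region_map)))
  if (!all(as.character(labs) %in% names(region_tensors)))
    stop("every region label needs a tensor in `region_tensors`", call. = FALSE)
  for (nm in names(region_tensors)) {
    D <- region_tensors[[nm]]
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
      stop("region tensor ", nm, " is not symmetric", call. = FALSE)
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
      stop("region tensor ", nm, " is not positive semi-definite",
           call. = FALSE)
  }
  structure(list(shape = shape, n_directions = as.integer(n_directions),
                 bval = bval, s0 = s0, region_map = region_map,
                 region_tensors = region_tensors,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "phantom_spec")
}

# concentric disks: 1 = background, 2 = annulus, 3 = inner disk
concentric_region_map <- function(shape) {
  H <- shape[1L]; W <- shape[2L]
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  r <- sqrt(outer((seq_len(H) - ci)^2, (seq_len(W) - cj)^2, `+`))
  rmin <- min(H, W)
  map <- matrix(1L, H, W)
  map[r <= 0.32 * rmin] <- 2L
  map[r <= 0.15 * rmin] <- 3L
  map
}

# isotropic background, prolate annulus (x axis), prolate core (y axis);
# tensors in mm^2/s
default_region_tensors <- function() {
  list(`1` = diag(c(0.9, 0.9, 0.9)) * 1e-3,
       `2` = diag(c(1.7, 0.3, 0.3)) * 1e-3,
       `3` = diag(c(0.3, 1.5, 0.3)) * 1e-3)
}

#' Deterministic quasi-uniform directions on the half-sphere
#'
#' Fibonacci-lattice points on the upper hemisphere (z >= 0), a standard
#' deterministic scheme for approximately uniform gradient tables.
#'
#' @param q number of directions.
#' @return 3 x q matrix of unit vectors.
#' @export
halfsphere_directions <- function(q) {
  k <- seq_len(q)
  z <- (k - 0.5) / q
  phi <- k * pi * (3 - sqrt(5))
  s <- sqrt(1 - z^2)
  rbind(s * cos(phi), s * sin(phi), z)
}

#' Simulate a noise-free multi-direction DWI stack from a phantom
#'
#' Single-tensor signal model per pixel and direction g:
#' `S = s0 * exp(-b * t(g) %*% D %*% g)`. One b = 0 volume is prepended to
#' `n_directions` volumes at `bval`. Ground-truth FA and ADC (mean
#' diffusivity) images are computed analytically from the region tensors.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (noise-free [dwi_stack()]), `fa` (H x W matrix),
#'   `adc` (H x W matrix, mm^2/s), `region_map`, and `spec`.
#' @export
simulate_dwi <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$shape[1L]; W <- spec$shape[2L]; q <- spec$n_directions
  dirs <- halfsphere_directions(q)
  bvecs <- cbind(c(0, 0, 0), dirs)
  bvals <- c(0, rep(spec$bval, q))
  labs <- sort(unique(as.integer(spec$region_map)))
  # per-region attenuation for each direction
  atten <- matrix(0, length(labs), q + 1L)
  fa_by <- adc_by <- numeric(length(labs))
  for (k in seq_along(labs)) {
    D <- spec$region_tensors[[as.character(labs[k])]]
    atten[k, ] <- exp(-bvals * colSums(bvecs * (D %*% bvecs)))
    ev <- pmax(eigen(D, symmetric = TRUE, only.values = TRUE)$values, 0)
    fa_by[k] <- fa_from_eigenvalues(ev)
    adc_by[k] <- mean(ev)
  }
  idx <- match(as.integer(spec$region_map), labs)
  ints <- array(0, c(H, W, q + 1L))
  for (v in seq_len(q + 1L))
    ints[, , v] <- spec$s0 * matrix(atten[idx, v], H, W)
  list(stack = dwi_stack(ints, bvals, bvecs),
       fa = matrix(fa_by[idx], H, W),
       adc = matrix(adc_by[idx], H, W),
       region_map = spec$region_map, spec = spec)
}

#' Add Rician noise to a magnitude image stack
#'
#' Each intensity v is replaced by `sqrt((v + n1)^2 + n2^2)` with n1, n2
#' i.i.d. Gaussian of standard deviation `noise_level * max(intensities)`
#' (noise level relative to peak). `noise_level = 0` returns the input
#' unchanged. Reproducible given `seed`; the global RNG state is restored.
#'
#' @param stack a [dwi_stack()].
#' @param noise_level relative noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return noisy [dwi_stack()].
#' @export
add_rician_noise <- function(stack, noise_level, seed = 1L) {
  stopifnot(inherits(stack, "dwi_stack"))
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  if (noise_level == 0) return(stack)
  sdev <- noise_level * max(stack$intensities)
  n <- length(stack$intensities)
  noisy <- with_seed(seed, {
    n1 <- stats::rnorm(n, sd = sdev)
    n2 <- stats::rnorm(n, sd = sdev)
    sqrt((as.numeric(stack$intensities) + n1)^2 + n2^2)
  })
  with_intensities(stack, array(noisy, dim(stack$intensities)))
}

#' Synthetic stroke phantom with infarct core / penumbra ADC contrast
#'
#' Concentric lesion geometry: a core disk (restricted diffusion) inside a
#' penumbra annulus, embedded in normal tissue, each region with a uniform
#' isotropic ADC. Also returns a two-volume DWI stack (b = 0 and `bval`)
#' whose mono-exponential decay matches the ADC map exactly, so a two-point
#' ADC computation recovers the region values.
#'
#' @param core_adc,penumbra_adc,normal_adc region ADC values in mm^2/s; must
#'   satisfy `0 < core_adc < penumbra_adc < normal_adc`.
#' @param shape length-2 image size in pixels.
#' @param core_radius,penumbra_radius region radii in pixels (core_radius = 0
#'   gives a phantom with no core).
#' @param bval high b-value of the two-point acquisition (s/mm^2).
#' @param s0 baseline signal.
#' @return list with `adc` (H x W, mm^2/s), `masks` (logical matrices `core`,
#'   `penumbra`, `normal`, a partition of the image), `region_map`, and
#'   `stack` (two-volume [dwi_stack()]).
#' @export
make_stroke_phantom <- function(core_adc = 0.342e-3, penumbra_adc = 0.803e-3,
                                normal_adc = 1.1e-3, shape = c(64L, 64L),
                                core_radius = 0.12 * min(shape),
                                penumbra_radius = 0.28 * min(shape),
                                bval = 1000, s0 = 1) {
  if (!(core_adc > 0 && core_adc < penumbra_adc && penumbra_adc < normal_adc))
    stop("ADC ordering violated: need 0 < core < penumbra < normal",
         call. = FALSE)
  if (core_radius > penumbra_radius)
    stop("`core_radius` must not exceed `penumbra_radius`", call. = FALSE)
  H <- shape[1L]; W <- shape[2L]
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  r <- sqrt(outer((seq_len(H) - ci)^2, (seq_len(W) - cj)^2, `+`))
  core <- r <= core_radius
  penumbra <- r <= penumbra_radius & !core
  normal <- !core & !penumbra
  adc <- matrix(normal_adc, H, W)
  adc[penumbra] <- penumbra_adc
  adc[core] <- core_adc
  region_map <- matrix(1L, H, W)
  region_map[penumbra] <- 2L
  region_map[core] <- 3L
  ints <- array(0, c(H, W, 2L))
  ints[, , 1L] <- s0
  ints[, , 2L] <- s0 * exp(-bval * adc)
  stack <- dwi_stack(ints, bvals = c(0, bval),
                     bvecs = cbind(c(0, 0, 0), c(1, 0, 0)))
  list(adc = adc, masks = list(core = core, penumbra = penumbra,
                               normal = normal),
       region_map = region_map, stack = stack)
}

#' Simulate a diagnostic cohort
#'
#' Draws each patient's true penumbra status as Bernoulli(`prevalence`) and a
#' binary modality call with the given sensitivity (detection probability
#' given disease) and specificity (correct-negative probability given no
#' disease). Reproducible given `seed`.
#'
#' @param n_patients cohort size, >= 1.
#' @param prevalence probability a patient truly has the condition.
#' @param sens,spec modality sensitivity and specificity, each in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with columns `patient_id`, `truth`, `call` (0/1).
#' @export
simulate_cohort <- function(n_patients, prevalence, sens, spec, seed = 1L) {
  if (n_patients < 1L) stop("`n_patients` must be >= 1", call. = FALSE)
  p <- c(prevalence, sens, spec)
  if (any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    truth <- stats::rbinom(n_patients, 1L, prevalence)
    call <- ifelse(truth == 1L,
                   stats::rbinom(n_patients, 1L, sens),
                   1L - stats::rbinom(n_patients, 1L, spec))
    data.frame(patient_id = seq_len(n_patients), truth = truth, call = call)
  })
}

# evaluate expr with a temporary RNG seed, restoring the global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
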