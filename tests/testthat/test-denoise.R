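test_that("universal threshold follows q * sigma * sqrt(2 ln n)", {
  expect_identical(universal_threshold(0, 100, 3), 0)
  # direct evaluation of the formula at sigma 0.05, n = 32*32*6
  expect_equal(universal_threshold(0.05, 6144, 1), 0.2088448141,
               tolerance = 1e-9)
  expect_equal(universal_threshold(0.05, 6144, 2),
               2 * universal_threshold(0.05, 6144, 1))
  expect_error(universal_threshold(0.05, 0, 1), "positive")
})

test_that("global stage is the identity at sigma = 0 and reduces noise", {
  ph <- tiny_phantom()
  cfg0 <- denoise_config(sigma = 0)
  out0 <- global_stage(ph$stack, cfg0)
  expect_lt(max(abs(out0$intensities - ph$stack$intensities)), 1e-8)

  noisy <- add_rician_noise(ph$stack, 0.05, seed = 2)
  out <- global_stage(noisy, denoise_config(sigma = 0.05))
  expect_gt(psnr(ph$stack, out), psnr(ph$stack, noisy))
  expect_true(all(out$intensities >= 0))

  # constant stack: thresholding kills the noise components
  const <- dwi_stack(array(0.5, c(16, 16, 4)), c(0, rep(1000, 3)),
                     cbind(c(0, 0, 0), halfsphere_directions(3)))
  cnoisy <- add_rician_noise(const, 0.05, seed = 3)
  cout <- global_stage(cnoisy, denoise_config(sigma = 0.05 * 0.5))
  expect_lt(stats::var(as.numeric(cout$intensities)),
            stats::var(as.numeric(cnoisy$intensities)))
})

test_that("block distance is the mean squared difference", {
  a <- array(0.3, c(3, 3, 4))
  expect_identical(block_distance(a, a), 0)
  expect_equal(block_distance(a, a + 0.1), 0.01, tolerance = 1e-12)
  set.seed(4)
  x <- array(rnorm(36), c(3, 3, 4)); y <- array(rnorm(36), c(3, 3, 4))
  acc <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:4) acc <- acc + (x[i,j,k] - y[i,j,k])^2
  expect_equal(block_distance(x, y), acc / 36, tolerance = 1e-12)
  expect_error(block_distance(x, array(0, c(2, 2, 2))), "shape")
})

test_that("block matching equals the exhaustive-scan oracle", {
  set.seed(6)
  guide <- random_stack(12, 12, 3, seed = 6)
  cfg <- denoise_config(sigma = 0.05, m = 3, search_radius = 4,
                        tau_d = 0.08, l_max = 6, n_step = 2)
  for (ref in list(c(1, 1), c(5, 7), c(10, 10))) {
    got <- find_similar_blocks(guide, ref, cfg)
    want <- oracle_match_blocks(guide$intensities, ref, 3, 4, 0.08, 6)
    expect_equal(matrix(as.numeric(got$coords), ncol = 2),
                 matrix(as.numeric(want), ncol = 2))
    expect_identical(got$coords[1, ], as.integer(ref))
  }
  expect_error(find_similar_blocks(guide, c(11, 11), cfg), "inside")
})

test_that("block matching degenerate cases: constant image and tau_d = 0", {
  const <- dwi_stack(array(1, c(10, 10, 2)), c(0, 1000),
                     cbind(c(0, 0, 0), c(1, 0, 0)))
  cfg <- denoise_config(sigma = 0.05, m = 2, search_radius = 3,
                        tau_d = 1, l_max = 5)
  grp <- find_similar_blocks(const, c(4, 4), cfg)
  expect_identical(grp$L, 5L)
  expect_identical(grp$coords[1, ], c(4L, 4L))
  # all distances are 0, so the rest follow in raster order within the window
  rest <- grp$coords[-1, , drop = FALSE]
  keys <- (rest[, 1] - 1) * 10 + (rest[, 2] - 1)
  expect_true(all(diff(keys) > 0))

  dist_img <- random_stack(10, 10, 2, seed = 8)
  cfg0 <- denoise_config(sigma = 0.05, m = 2, search_radius = 3, tau_d = 0,
                         l_max = 5)
  solo <- find_similar_blocks(dist_img, c(4, 4), cfg0)
  expect_identical(solo$L, 1L)
})

test_that("group denoising projects onto the guide basis and thresholds", {
  set.seed(10)
  # sigma = 0: exact reconstruction
  g <- array(runif(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  cfg0 <- denoise_config(sigma = 0, m = 2)
  out0 <- denoise_group(g, g, cfg0)
  expect_lt(max(abs(out0$denoised - g)), 1e-8)

  # infinite threshold: everything zeroed
  cfg_inf <- denoise_config(sigma = 1e6, m = 2, q_local = 1e6)
  out_inf <- denoise_group(g + array(rnorm(16, sd = 0.1), dim(g)), g, cfg_inf)
  expect_identical(out_inf$l0, 0L)
  expect_equal(out_inf$denoised, array(0, dim(g)))
  expect_equal(out_inf$weight, 1)

  # projection coefficients match the quadruple-loop oracle
  noisy_g <- g + array(rnorm(16, sd = 0.05), dim(g))
  bases <- lapply(1:4, function(n) {
    un <- oracle_unfold4(g, n)
    svd(un, nu = nrow(un), nv = 0)$u
  })
  sn_oracle <- oracle_project4(noisy_g, bases, transpose = TRUE)
  cfg <- denoise_config(sigma = 0.05, m = 2, q_local = 2.2)
  tau <- universal_threshold(0.05, 16, 2.2)
  sn_thresh <- sn_oracle * (abs(sn_oracle) >= tau)
  out <- denoise_group(noisy_g, g, cfg)
  expect_equal(out$l0, sum(sn_thresh != 0))
  expect_equal(out$denoised, oracle_project4(sn_thresh, bases, FALSE),
               tolerance = 1e-10)
  expect_equal(out$weight, 1 / (1 + out$l0))
})

test_that("local stage covers every pixel and is the identity at sigma = 0", {
  ph <- tiny_phantom(shape = c(17L, 19L), q = 6L)  # odd sizes stress coverage
  cfg <- denoise_config(sigma = 0, m = 4, n_step = 3)
  out <- local_stage(ph$stack, ph$stack, cfg)
  expect_lt(max(abs(out$intensities - ph$stack$intensities)), 1e-7)
  expect_error(local_stage(ph$stack, tiny_phantom(c(16L, 16L), 6L)$stack, cfg),
               "shape")
  small <- dwi_stack(array(1, c(3, 3, 2)), c(0, 1000),
                     cbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(local_stage(small, small, denoise_config(sigma = 0, m = 4)),
               "smaller")
})

test_that("local stage matches the straight-line loop reference", {
  ph <- simulate_dwi(phantom_spec(shape = c(8L, 8L), n_directions = 1L))
  noisy <- add_rician_noise(ph$stack, 0.05, seed = 20)
  guide <- global_stage(noisy, denoise_config(sigma = 0.05))
  cfg <- denoise_config(sigma = 0.05, m = 2, search_radius = 2,
                        l_max = 4, n_step = 2)
  got <- local_stage(noisy, guide, cfg)
  want <- oracle_local_stage(noisy$intensities, guide$intensities,
                             sigma = 0.05, q_local = cfg$q_local, m = 2,
                             radius = 2, tau_d = cfg$tau_d, l_max = 4,
                             n_step = 2)
  expect_equal(got$intensities, want, tolerance = 1e-10)
})

test_that("full pipeline is deterministic, nonnegative, and beats its stages", {
  ph <- tiny_phantom()
  noisy <- add_rician_noise(ph$stack, 0.05, seed = 21)
  cfg <- denoise_config(sigma = 0.05)
  fit1 <- gl_hosvd(noisy, cfg)
  fit2 <- gl_hosvd(noisy, cfg)
  expect_identical(fit1$denoised$intensities, fit2$denoised$intensities)
  expect_true(all(fit1$denoised$intensities >= 0))
  expect_gt(psnr(ph$stack, fit1$denoised), psnr(ph$stack, fit1$prefiltered))
  expect_gt(psnr(ph$stack, fit1$prefiltered), psnr(ph$stack, noisy))

  # sigma = 0 end-to-end identity
  fit0 <- gl_hosvd(ph$stack, denoise_config(sigma = 0))
  expect_lt(max(abs(fit0$denoised$intensities - ph$stack$intensities)), 1e-7)
})

test_that("denser sliding steps do not lose quality", {
  ph <- tiny_phantom(shape = c(16L, 16L), q = 4L)
  noisy <- add_rician_noise(ph$stack, 0.05, seed = 22)
  p1 <- psnr(ph$stack, gl_hosvd(noisy, denoise_config(sigma = 0.05, m = 4,
                                                      n_step = 1))$denoised)
  pm <- psnr(ph$stack, gl_hosvd(noisy, denoise_config(sigma = 0.05, m = 4,
                                                      n_step = 4))$denoised)
  expect_gte(p1, pm - 0.5)
})

test_that("gl_hosvd methods report sensibly", {
  ph <- tiny_phantom(shape = c(16L, 16L), q = 4L)
  noisy <- add_rician_noise(ph$stack, 0.05, seed = 23)
  fit <- gl_hosvd(noisy, denoise_config(sigma = 0.05))
  expect_output(print(fit), "GL-HOSVD")
  s <- summary(fit, reference = ph$stack)
  expect_true(s$psnr[["denoised"]] > s$psnr[["noisy"]])
  expect_identical(dim(residuals(fit)), dim(noisy$intensities))
  expect_equal(residuals(fit),
               noisy$intensities - fit$denoised$intensities)
})
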