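# Independent brute-force oracles. Everything here is written with explicit
# loops (plus base svd/eigen on loop-built matrices) and never calls the
# package's tensor plumbing, so the two routes stay independent.

# sum of the mode-n fibers of a 3-way tensor, by explicit loops
oracle_fiber_sums <- function(tensor, mode) {
  d <- dim(tensor)
  out <- numeric(d[mode])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)[mode]
    out[idx] <- out[idx] + tensor[i, j, k]
  }
  out
}

# n-mode product of a 3-way tensor by triple-loop summation
oracle_mode_product3 <- function(tensor, mat, mode) {
  d <- dim(tensor)
  d2 <- d; d2[mode] <- nrow(mat)
  out <- array(0, d2)
  for (i in seq_len(d2[1])) for (j in seq_len(d2[2])) for (k in seq_len(d2[3])) {
    acc <- 0
    for (s in seq_len(d[mode])) {
      src <- c(i, j, k); src[mode] <- s
      tgt <- c(i, j, k)[mode]
      acc <- acc + mat[tgt, s] * tensor[src[1], src[2], src[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

# mode-n unfolding built element by element (column-major over other modes,
# lowest remaining mode cycling fastest)
oracle_unfold <- function(tensor, mode) {
  d <- dim(tensor)
  others <- setdiff(seq_along(d), mode)
  out <- matrix(0, d[mode], prod(d[others]))
  idx_grid <- as.matrix(expand.grid(lapply(d[others], seq_len)))
  for (col in seq_len(nrow(idx_grid))) {
    for (r in seq_len(d[mode])) {
      full <- integer(length(d))
      full[mode] <- r
      full[others] <- idx_grid[col, ]
      out[r, col] <- do.call(`[`, c(list(tensor), as.list(full)))
    }
  }
  out
}

# orthonormal basis of a mode's unfolding via eigendecomposition of the
# Gram matrix (independent route to the left singular vectors)
oracle_gram_basis <- function(tensor, mode) {
  un <- oracle_unfold(tensor, mode)
  eigen(un %*% t(un), symmetric = TRUE)$vectors
}

# exhaustive block matcher written with plain loops
oracle_match_blocks <- function(guide_arr, ref, m, radius, tau_d, l_max) {
  d <- dim(guide_arr)
  H <- d[1]; W <- d[2]; Q <- d[3]
  block <- function(i, j) guide_arr[i:(i + m - 1), j:(j + m - 1), , drop = FALSE]
  rb <- block(ref[1], ref[2])
  cand <- list(); dist <- numeric(0); key <- numeric(0)
  for (i in max(1, ref[1] - radius):min(H - m + 1, ref[1] + radius)) {
    for (j in max(1, ref[2] - radius):min(W - m + 1, ref[2] + radius)) {
      if (i == ref[1] && j == ref[2]) next
      dd <- sum((block(i, j) - rb)^2) / (m * m * Q)
      if (dd <= tau_d) {
        cand[[length(cand) + 1]] <- c(i, j)
        dist <- c(dist, dd)
        key <- c(key, (i - 1) * W + (j - 1))
      }
    }
  }
  ord <- order(dist, key)
  coords <- rbind(ref, do.call(rbind, cand[ord]))
  coords <- coords[seq_len(min(nrow(coords), l_max)), , drop = FALSE]
  dimnames(coords) <- NULL
  coords
}

# order-4 HOSVD basis of a loop-built unfolding
oracle_unfold4 <- function(tensor, mode) {
  d <- dim(tensor)
  others <- setdiff(1:4, mode)
  out <- matrix(0, d[mode], prod(d[others]))
  grid <- as.matrix(expand.grid(lapply(d[others], seq_len)))
  for (col in seq_len(nrow(grid))) {
    for (r in seq_len(d[mode])) {
      full <- integer(4)
      full[mode] <- r
      full[others] <- grid[col, ]
      out[r, col] <- tensor[full[1], full[2], full[3], full[4]]
    }
  }
  out
}

# project an order-4 tensor onto bases by quadruple-loop summation
oracle_project4 <- function(tensor, bases, transpose = TRUE) {
  d <- dim(tensor)
  dims_out <- if (transpose) sapply(bases, ncol) else sapply(bases, nrow)
  out <- array(0, dims_out)
  grid_in <- as.matrix(expand.grid(lapply(d, seq_len)))
  grid_out <- as.matrix(expand.grid(lapply(dims_out, seq_len)))
  for (po in seq_len(nrow(grid_out))) {
    p <- grid_out[po, ]
    acc <- 0
    for (pi in seq_len(nrow(grid_in))) {
      a <- grid_in[pi, ]
      w <- 1
      for (n in 1:4) {
        w <- w * if (transpose) bases[[n]][a[n], p[n]] else bases[[n]][p[n], a[n]]
      }
      acc <- acc + w * tensor[a[1], a[2], a[3], a[4]]
    }
    out[p[1], p[2], p[3], p[4]] <- acc
  }
  out
}

# straight-line reference implementation of the whole local stage
oracle_local_stage <- function(noisy_arr, guide_arr, sigma, q_local, m,
                               radius, tau_d, l_max, n_step) {
  d <- dim(noisy_arr)
  H <- d[1]; W <- d[2]; Q <- d[3]
  pos_i <- unique(c(seq(1, H - m + 1, by = n_step), H - m + 1))
  pos_j <- unique(c(seq(1, W - m + 1, by = n_step), W - m + 1))
  num <- array(0, d); wt <- array(0, d)
  for (i in pos_i) for (j in pos_j) {
    coords <- oracle_match_blocks(guide_arr, c(i, j), m, radius, tau_d, l_max)
    L <- nrow(coords)
    gn <- array(0, c(m, m, Q, L)); gp <- gn
    for (l in seq_len(L)) {
      a <- coords[l, 1]; b <- coords[l, 2]
      gn[, , , l] <- noisy_arr[a:(a + m - 1), b:(b + m - 1), ]
      gp[, , , l] <- guide_arr[a:(a + m - 1), b:(b + m - 1), ]
    }
    bases <- lapply(1:4, function(n) {
      un <- oracle_unfold4(gp, n)
      svd(un, nu = nrow(un), nv = 0)$u
    })
    sn <- oracle_project4(gn, bases, transpose = TRUE)
    tau <- q_local * sigma * sqrt(2 * log(m * m * Q * L))
    sn[abs(sn) < tau] <- 0
    den <- oracle_project4(sn, bases, transpose = FALSE)
    theta <- 1 / (1 + sum(sn != 0))
    for (l in seq_len(L)) {
      a <- coords[l, 1]; b <- coords[l, 2]
      for (u in 0:(m - 1)) for (v in 0:(m - 1)) for (q in 1:Q) {
        num[a + u, b + v, q] <- num[a + u, b + v, q] +
          theta * den[u + 1, v + 1, q, l]
        wt[a + u, b + v, q] <- wt[a + u, b + v, q] + theta
      }
    }
  }
  pmax(num / wt, 0)
}

# small reusable fixtures ------------------------------------------------------

tiny_phantom <- function(shape = c(32L, 32L), q = 6L) {
  simulate_dwi(phantom_spec(shape = shape, n_directions = q))
}

random_stack <- function(H, W, Q, seed = 1) {
  set.seed(seed)
  ints <- array(runif(H * W * Q), c(H, W, Q))
  dirs <- halfsphere_directions(Q - 1L)
  dwi_stack(ints, bvals = c(0, rep(1000, Q - 1L)),
            bvecs = cbind(c(0, 0, 0), dirs))
}

with_offset <- function(stack, delta) {
  out <- stack
  out$intensities <- out$intensities + delta
  out
}

fa_map_of <- function(stack) {
  f <- fit_dti(stack)
  fa <- f$fa
  fa[!f$mask] <- 0
  fa
}
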