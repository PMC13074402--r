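# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the oracles are deliberately written independently of the
# package's implementation paths (direct loops, enumeration, or a different
# algorithm family).

rand_cx_mat <- function(n, sd = 1) {
  matrix(complex(real = rnorm(n * n, sd = sd),
                 imaginary = rnorm(n * n, sd = sd)), n, n)
}

rand_cx_cube <- function(n, L, sd = 1) {
  array(complex(real = rnorm(n * n * L, sd = sd),
                imaginary = rnorm(n * n * L, sd = sd)), c(n, n, L))
}

# small synthetic multicoil dataset (via the package generator)
tiny_training_set <- function(N0 = 16, L = 2, T_sets = 3, seed = 7) {
  assemble_training_set(phantom_spec(N0 = N0, L = L, T_sets = T_sets,
                                     seed = seed))
}

# --- integer rounding oracle: exhaustive search over the integer simplex ----
# all nonnegative integer vectors of length n summing to total
enum_compositions <- function(n, total) {
  if (n == 1) return(matrix(total, 1, 1))
  out <- NULL
  for (k in 0:total) {
    rest <- enum_compositions(n - 1, total - k)
    out <- rbind(out, cbind(k, rest))
  }
  unname(out)
}

exhaustive_round_cost <- function(target, total) {
  qs <- enum_compositions(length(target), total)
  costs <- apply(qs, 1, function(q) sum(abs(q - target)))
  min(costs)
}

# --- SENSE-TV convex oracle: Condat-Vu primal-dual, an algorithm family ----
# independent of the package's ADMM path
cv_sense_tv_oracle <- function(d, maps, w, lambda, N, N0, iters = 20000) {
  a2 <- w
  Lg <- 2 * max(a2) * max(apply(abs(maps)^2, c(1, 2), sum))
  sig <- 1 / sqrt(8)
  tau <- 1 / (Lg / 2 + sig * 8)
  x <- matrix(0 + 0i, N0, N0)
  y <- array(0 + 0i, c(N0, N0, 2))
  for (k in seq_len(iters)) {
    r <- forward_model_apply(x, maps, N) - d
    g <- 2 * forward_model_adjoint(array(a2, dim(r)) * r, maps)
    xn <- x - tau * (g + finite_difference_adjoint(y))
    v <- y + sig * finite_difference_apply(2 * xn - x)
    scl <- pmin(1, lambda / pmax(abs(v), 1e-300))
    y <- v * array(scl, dim(v))
    x <- xn
  }
  x
}

sense_tv_obj_direct <- function(x, d, maps, w, lambda, N) {
  r <- forward_model_apply(x, maps, N) - d
  sum(array(w, dim(r)) * abs(r)^2) +
    lambda * sum(abs(finite_difference_apply(x)))
}

# --- SSIM oracle: direct double-loop implementation of the windowed stats ---
ssim_direct <- function(x, r, K1 = 0.01, K2 = 0.03, win = 11, sigma = 1.5) {
  X <- abs(x); R <- abs(r)
  range_r <- max(R)
  C1 <- (K1 * range_r)^2; C2 <- (K2 * range_r)^2
  half <- (win - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2)); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  n1 <- nrow(X); n2 <- ncol(X)
  vals <- c()
  for (i in seq_len(n1 - win + 1)) {
    for (j in seq_len(n2 - win + 1)) {
      px <- X[i:(i + win - 1), j:(j + win - 1)]
      pr <- R[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(G * px); mr <- sum(G * pr)
      vx <- sum(G * px^2) - mx^2
      vr <- sum(G * pr^2) - mr^2
      cxr <- sum(G * px * pr) - mx * mr
      vals <- c(vals, ((2 * mx * mr + C1) * (2 * cxr + C2)) /
                  ((mx^2 + mr^2 + C1) * (vx + vr + C2)))
    }
  }
  mean(vals)
}

# 2D circular convolution by direct summation (order N^4; tiny grids only).
# `offset` shifts the kernel index, matching the centered-grid convention
# (offset = n/2 puts the kernel origin at array index n/2 + 1).
conv_circ_direct <- function(a, b, offset = 0) {
  n <- nrow(a)
  out <- matrix(0 + 0i, n, n)
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    acc <- 0 + 0i
    for (p in 0:(n - 1)) for (q in 0:(n - 1)) {
      acc <- acc + a[p + 1, q + 1] *
        b[((i - p + offset) %% n) + 1, ((j - q + offset) %% n) + 1]
    }
    out[i + 1, j + 1] <- acc
  }
  out
}
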