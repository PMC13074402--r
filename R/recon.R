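# Reconstruction operators and the three reconstructor families.
#
# Every reconstructor maps an N x N x L noisy acquisition to an N0 x N0
# complex image, regardless of the acquisition grid size N, so that designs
# with different N are directly comparable.

#' Apply the SENSE low-resolution forward model E
#'
#' Per channel: multiply the image by the coil sensitivity, take the unitary
#' centered Fourier transform on the `N0` grid, and crop to the central
#' `N x N` block.
#'
#' @param x complex `N0 x N0` image
#' @param maps complex `N0 x N0 x L` sensitivity maps
#' @param N acquisition grid size
#' @return complex `N x N x L` k-space array
#' @export
forward_model_apply <- function(x, maps, N) {
  if (!all(dim(x) == dim(maps)[1:2])) stop("image and maps shapes differ")
  map_channels(maps, function(S) crop_center(ft2c(S * x), N))
}

#' Adjoint of the SENSE forward model
#'
#' @param y complex `N x N x L` k-space array
#' @param maps complex `N0 x N0 x L` sensitivity maps
#' @return complex `N0 x N0` image; satisfies `<Ex, y> = <x, E^H y>`
#' @export
forward_model_adjoint <- function(y, maps) {
  N0 <- dim(maps)[1]
  L <- dim(maps)[3]
  out <- matrix(0 + 0i, N0, N0)
  for (l in seq_len(L))
    out <- out + Conj(maps[, , l]) * ift2c(pad_center(y[, , l], N0))
  out
}

#' Periodic first-difference operator D
#'
#' Stacks horizontal and vertical first differences with periodic boundary
#' conditions; `sum(abs(finite_difference_apply(x)))` is the anisotropic total
#' variation of `x`.
#'
#' @param x complex matrix
#' @return complex array `nrow x ncol x 2` (row differences, column
#'   differences)
#' @export
finite_difference_apply <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  d1 <- x[c(seq_len(n1)[-1], 1), , drop = FALSE] - x
  d2 <- x[, c(seq_len(n2)[-1], 1), drop = FALSE] - x
  array(c(d1, d2), c(n1, n2, 2))
}

#' Adjoint of the periodic first-difference operator
#'
#' @param y complex array `n1 x n2 x 2`
#' @return complex matrix `n1 x n2`
#' @export
finite_difference_adjoint <- function(y) {
  d1 <- y[, , 1]; d2 <- y[, , 2]
  n1 <- nrow(d1); n2 <- ncol(d1)
  (d1[c(n1, 1:(n1 - 1)), , drop = FALSE] - d1) +
    (d2[, c(n2, 1:(n2 - 1)), drop = FALSE] - d2)
}

#' Zero-padded inverse Fourier reconstruction per channel
#'
#' Pads `N x N x L` k-space to the `N0` grid and applies the unitary inverse
#' transform channelwise.
#'
#' @param d complex `N x N x L` k-space
#' @param N0 output grid size
#' @return complex `N0 x N0 x L` channel images
#' @export
zero_pad_recon <- function(d, N0) {
  map_channels(d, function(m) ift2c(pad_center(m, N0)))
}

#' SENSE-style unit-gain coil combination
#'
#' `x = sum(conj(S_l) f_l) / sum(|S_l|^2)`, with zero output where the
#' sensitivity energy falls below a floor.
#'
#' @param channel_images complex `N0 x N0 x L`
#' @param maps complex `N0 x N0 x L`
#' @param eps denominator floor
#' @return complex `N0 x N0` combined image
#' @export
coil_combine <- function(channel_images, maps, eps = 1e-8) {
  num <- matrix(0 + 0i, dim(maps)[1], dim(maps)[2])
  den <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (l in seq_len(dim(maps)[3])) {
    num <- num + Conj(maps[, , l]) * channel_images[, , l]
    den <- den + abs(maps[, , l])^2
  }
  out <- num
  ok <- den > eps
  out[ok] <- num[ok] / den[ok]
  out[!ok] <- 0
  out
}

# ---------------------------------------------------------------------------
# Reconstructor objects

#' Apodized (windowed Fourier) reconstructor
#'
#' Multiplies the measured k-space by a real positive `N x N` window prior to
#' zero-padded Fourier reconstruction and SENSE coil combination. The window
#' values are the trainable parameters; positivity is maintained by projection
#' onto `h >= eps`.
#'
#' @param N,N0 acquisition and output grid sizes
#' @param maps sensitivity maps (`N0 x N0 x L`)
#' @param h initial window (`N x N` positive); defaults to flat
#' @param eps positivity floor for the window
#' @return object of class `c("recon_apodized", "reconstructor")`
#' @export
recon_apodized <- function(N, N0, maps, h = NULL, eps = 1e-6) {
  if (is.null(h)) h <- matrix(1, N, N)
  h <- pmax(h, eps)
  structure(list(kind = "apodized", N = N, N0 = N0, maps = maps, h = h,
                 eps = eps),
            class = c("recon_apodized", "reconstructor"))
}

#' SENSE reconstructor with total-variation regularization
#'
#' Solves `argmin_x || sqrt(w) (E x - d) ||_2^2 + lambda ||D x||_1` by a fixed
#' number of ADMM iterations. The data-term weights are `sqrt(w_m)` per line
#' so the quadratic term matches the negative log-likelihood of noise with
#' variance `sigma^2 / w_m`; set `literal_w = TRUE` to weight by `w_m`
#' instead. `lambda` is stored in log-space so gradient updates preserve
#' positivity.
#'
#' @param lambda TV regularization parameter (positive)
#' @param maps sensitivity maps
#' @param N,N0 grid sizes
#' @param rho ADMM penalty parameter
#' @param iterations fixed ADMM iteration count
#' @param cg_iters,cg_tol conjugate-gradient budget for the x-update
#' @param literal_w use `w` (not `sqrt(w)`) as the elementwise data weight
#' @return object of class `c("recon_sense_tv", "reconstructor")`
#' @export
recon_sense_tv <- function(lambda, maps, N, N0, rho = 0.1, iterations = 50L,
                           cg_iters = 10L, cg_tol = 1e-8, literal_w = FALSE) {
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(kind = "sense_tv", log_lambda = log(lambda), maps = maps,
                 N = N, N0 = N0, rho = rho, iterations = as.integer(iterations),
                 cg_iters = as.integer(cg_iters), cg_tol = cg_tol,
                 literal_w = literal_w),
            class = c("recon_sense_tv", "reconstructor"))
}

# Data-term weight per line: sqrt(w) by default (statistically matched), or
# w when reproducing the literal printed objective.
data_weights <- function(recon, w) if (isTRUE(recon$literal_w)) w else sqrt(w)

#' Reconstruct an image from a noisy acquisition
#'
#' @param recon a reconstructor object
#' @param acq a `noisy_acquisition` (or a list with fields `d` and `pattern`)
#' @param ... passed to methods
#' @return complex `N0 x N0` image
#' @export
reconstruct <- function(recon, acq, ...) UseMethod("reconstruct")

#' @rdname reconstruct
#' @export
reconstruct.recon_apodized <- function(recon, acq, ...) {
  d <- acq$d
  if (dim(d)[1] != recon$N) stop("acquisition grid does not match reconstructor")
  h <- pmax(recon$h, recon$eps)
  hd <- array(as.vector(h), dim(d)) * d   # window shared across channels
  coil_combine(zero_pad_recon(hd, recon$N0), recon$maps)
}

#' @rdname reconstruct
#' @export
reconstruct.recon_sense_tv <- function(recon, acq, ...) {
  res <- sense_tv_solve(recon, acq$d, acq$pattern$w)
  res$x
}

#' Run the weighted SENSE-TV ADMM solver, returning diagnostics
#'
#' @param recon a `recon_sense_tv`
#' @param d complex `N x N x L` data
#' @param w effective averages (length `N`)
#' @return list with `x` (image), `objective` (per-iteration trace),
#'   `diverged` flag
#' @export
sense_tv_solve <- function(recon, d, w) {
  out <- admm_sense_tv_cpp(d, recon$maps, data_weights(recon, w),
                           exp(recon$log_lambda), recon$rho,
                           recon$iterations, recon$cg_iters, recon$cg_tol)
  obj <- as.numeric(out$objective)
  # divergence heuristic: objective increases for 10 consecutive iterations
  div <- FALSE
  if (length(obj) > 10) {
    inc <- diff(obj) > 1e-12 * pmax(abs(obj[-length(obj)]), 1)
    run <- rle(inc)
    div <- any(run$values & run$lengths >= 10)
  }
  list(x = out$x, objective = obj, diverged = div)
}

#' Evaluate the SENSE-TV objective at an image
#'
#' `|| wdata * (E x - d) ||_2^2 + lambda ||D x||_1` with `wdata` the per-line
#' data weights of the reconstructor.
#'
#' @param recon a `recon_sense_tv`
#' @param x complex `N0 x N0` image
#' @param d complex `N x N x L` data
#' @param w effective averages
#' @return scalar objective value
#' @export
sense_tv_objective <- function(recon, x, d, w) {
  wd <- data_weights(recon, w)
  r <- forward_model_apply(x, recon$maps, recon$N) - d
  r <- array(wd, dim(r)) * r
  sum(abs(r)^2) + exp(recon$log_lambda) * sum(abs(finite_difference_apply(x)))
}

# ---------------------------------------------------------------------------
# Gradients of the training loss J = ||x_hat - r||_2^2

#' Loss and gradients for the apodized reconstructor (closed form)
#'
#' The apodized reconstruction is linear in the data, so the gradients of the
#' squared-error training loss with respect to the window values and the
#' effective averages are available in closed form. The dependence of the
#' loss on `w` enters through the noise scaling `d = s + z / sqrt(w)`.
#'
#' @param recon a `recon_apodized`
#' @param s_N noiseless cropped k-space `N x N x L`
#' @param z_N cropped unit-variance master noise `N x N x L` (times sigma)
#' @param w effective averages
#' @param r reference image `N0 x N0`
#' @param sigma noise standard deviation
#' @return list with `loss`, `grad_h` (`N x N`), `grad_w` (length `N`),
#'   `x` (reconstruction)
#' @export
apodized_loss_grad <- function(recon, s_N, z_N, w, r, sigma) {
  N <- recon$N; N0 <- recon$N0; maps <- recon$maps
  L <- dim(s_N)[3]
  scale <- sigma / sqrt(w)
  d <- s_N + array(scale, dim(s_N)) * z_N
  h <- pmax(recon$h, recon$eps)
  harr <- array(as.vector(h), dim(d))
  f <- zero_pad_recon(harr * d, N0)
  x <- coil_combine(f, maps)
  g <- x - r
  loss <- sum(abs(g)^2)
  # backprop: cotangent of x is 2 g under the real pairing Re<a, b>
  den <- matrix(0, N0, N0)
  for (l in seq_len(L)) den <- den + abs(maps[, , l])^2
  ok <- den > 1e-8
  xbar <- 2 * g
  xbar[ok] <- xbar[ok] / den[ok]
  xbar[!ok] <- 0
  grad_h <- matrix(0, N, N)
  dbar <- array(0 + 0i, dim(d))
  for (l in seq_len(L)) {
    fbar <- maps[, , l] * xbar                   # cotangent of channel image
    ybar <- crop_center(ft2c(fbar), N)           # adjoint of ift(pad(.))
    grad_h <- grad_h + Re(Conj(d[, , l]) * ybar)
    dbar[, , l] <- harr[, , l] * ybar
  }
  # dd/dw_m = -1/2 sigma w_m^{-3/2} z on line m
  dz <- Re(Conj(dbar) * z_N)
  per_line <- apply(dz, 1, sum)
  grad_w <- -0.5 * sigma * w^(-1.5) * per_line
  list(loss = loss, grad_h = grad_h, grad_w = grad_w, x = x)
}

#' Loss and gradients for the SENSE-TV reconstructor
#'
#' Runs the fixed-iteration ADMM forward pass and a hand-derived reverse-mode
#' sweep through the unrolled iterations (each conjugate-gradient solve is
#' treated as an exact linear solve), returning the gradient of
#' `J = ||x_hat - r||^2` with respect to `log(lambda)` and the effective
#' averages `w`. The `w` gradient includes both the data-weighting term and
#' the noise-scaling dependence of `d` on `w`.
#'
#' @inheritParams apodized_loss_grad
#' @param recon a `recon_sense_tv`
#' @return list with `loss`, `grad_log_lambda`, `grad_w`, `x`
#' @export
sense_tv_loss_grad <- function(recon, s_N, z_N, w, r, sigma) {
  out <- admm_sense_tv_grad_cpp(s_N, z_N, w, sigma, recon$maps,
                                exp(recon$log_lambda), recon$rho,
                                recon$iterations, recon$cg_iters, recon$cg_tol,
                                r, isTRUE(recon$literal_w))
  list(loss = out$loss,
       grad_log_lambda = out$grad_lambda * exp(recon$log_lambda),
       grad_w = as.numeric(out$grad_w),
       x = out$x)
}

#' Tune the ADMM penalty parameter on a representative instance
#'
#' Coarse logarithmic grid search minimizing NRMSE of the ADMM output against
#' the matched-resolution reference for one representative dataset; the best
#' `rho` is then frozen for all subsequent reconstructions at this
#' (noise level, N) combination.
#'
#' @param recon a `recon_sense_tv`
#' @param acq a `noisy_acquisition`
#' @param r reference image
#' @param grid candidate penalty values
#' @return the tuned `recon_sense_tv`
#' @export
tune_admm_rho <- function(recon, acq, r,
                          grid = 10^seq(-2, 3, by = 1)) {
  errs <- vapply(grid, function(rho) {
    rc <- recon; rc$rho <- rho
    nrmse(reconstruct(rc, acq), r)
  }, numeric(1))
  recon$rho <- grid[which.min(errs)]
  recon
}
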