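# Plugin interface for learned (CNN-style) reconstructors.
#
# A registered network maps the real and imaginary parts of the zero-padded
# per-channel images (an N0 x N0 x 2L real array) to the real and imaginary
# parts of a coil-combined image (N0 x N0 x 2). The package ships a
# weight-free linear stub that performs SENSE coil combination through this
# contract, so the plugin path is exercised end to end; training a deep
# network is left to the plugin provider.

#' CNN-plugin reconstructor
#'
#' @param network list with elements `forward(input, weights)` (input is an
#'   `N0 x N0 x 2L` real array, output an `N0 x N0 x 2` real array) and
#'   optionally `n_channels_in`
#' @param weights network weights, passed through to `forward`
#' @param maps sensitivity maps (`N0 x N0 x L`)
#' @param N,N0 grid sizes
#' @return object of class `c("recon_cnn", "reconstructor")`
#' @export
recon_cnn <- function(network, weights, maps, N, N0) {
  structure(list(kind = "cnn", network = network, weights = weights,
                 maps = maps, N = N, N0 = N0),
            class = c("recon_cnn", "reconstructor"))
}

#' @rdname reconstruct
#' @export
reconstruct.recon_cnn <- function(recon, acq, ...) {
  L <- dim(recon$maps)[3]
  imgs <- zero_pad_recon(acq$d, recon$N0)
  inp <- array(0, c(recon$N0, recon$N0, 2L * L))
  for (l in seq_len(L)) {
    inp[, , 2 * l - 1] <- Re(imgs[, , l])
    inp[, , 2 * l] <- Im(imgs[, , l])
  }
  if (!is.null(recon$network$n_channels_in) &&
      recon$network$n_channels_in != 2L * L)
    stop("network input channel count does not match 2L")
  out <- recon$network$forward(inp, recon$weights)
  if (!(length(dim(out)) == 3L && dim(out)[3] == 2L))
    stop("network must return an N0 x N0 x 2 real array")
  matrix(complex(real = out[, , 1], imaginary = out[, , 2]),
         recon$N0, recon$N0)
}

#' Weight-free coil-combination network stub
#'
#' Satisfies the CNN plugin contract (`2L` input channels, 2 output
#' channels) with a fixed linear map that reproduces [coil_combine()]; useful
#' as a contract check and as a deterministic baseline.
#'
#' @param maps sensitivity maps
#' @return a network list for [recon_cnn()]
#' @export
cnn_identity_stub <- function(maps) {
  L <- dim(maps)[3]
  list(
    n_channels_in = 2L * L,
    forward = function(input, weights) {
      N0 <- dim(input)[1]
      imgs <- array(0 + 0i, c(N0, N0, L))
      for (l in seq_len(L))
        imgs[, , l] <- input[, , 2 * l - 1] + 1i * input[, , 2 * l]
      x <- coil_combine(imgs, maps)
      array(c(Re(x), Im(x)), c(N0, N0, 2))
    })
}

#' Central finite-difference gradient of a scalar function
#'
#' Generic numerical gradient used as the independent cross-check of the
#' analytic gradients, and as the gradient provider for plugin reconstructors
#' that do not supply their own.
#'
#' @param f scalar-valued function of a numeric vector
#' @param x evaluation point
#' @param h step size
#' @return numeric gradient vector
#' @export
fd_gradient <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
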