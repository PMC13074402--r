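#' @useDynLib kcoverage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd optimize
NULL

# Centered-grid Fourier conventions
#
# All k-space and image grids in this package are stored in "centered" order:
# the index m runs over -N/2, ..., N/2-1 and maps to array index m + N/2 + 1,
# so the DC sample sits at index N/2 + 1. All grid sizes are even. Transforms
# are unitary (norm-preserving), so Parseval identities hold exactly and
# crop/zero-pad adjointness is scale-free.

#' Swap quadrants so that the DC sample moves between corner and center
#'
#' For even-length dimensions the forward and inverse shifts coincide, and the
#' package requires even grids throughout, so a single helper suffices.
#'
#' @param x matrix
#' @return matrix of the same shape with both halves swapped along each axis
#' @keywords internal
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  stopifnot(n1 %% 2L == 0L, n2 %% 2L == 0L)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2)), drop = FALSE]
}

#' Unitary centered 2D Fourier transform
#'
#' Maps a centered-order image to centered-order k-space with DC at index
#' N/2 + 1, scaled by 1/sqrt(N1*N2) so the transform is norm-preserving.
#'
#' @param x complex matrix in centered order
#' @return complex matrix, same shape
#' @export
ft2c <- function(x) {
  fftshift2(stats::fft(fftshift2(x))) / sqrt(length(x))
}

#' Unitary centered 2D inverse Fourier transform
#'
#' Inverse of [ft2c()].
#'
#' @param x complex matrix in centered order
#' @return complex matrix, same shape
#' @export
ift2c <- function(x) {
  fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Row/column indices of the centered N-subgrid inside an N0 grid
#' @keywords internal
center_idx <- function(N, N0) {
  (N0 / 2 - N / 2 + 1):(N0 / 2 + N / 2)
}

#' Extract the centered N x N block of a matrix
#' @keywords internal
crop_center <- function(x, N) {
  stopifnot(nrow(x) == ncol(x))
  idx <- center_idx(N, nrow(x))
  x[idx, idx, drop = FALSE]
}

#' Zero-pad a matrix into the center of an N0 x N0 grid
#' @keywords internal
pad_center <- function(x, N0) {
  N <- nrow(x)
  out <- matrix(0 + 0i, N0, N0)
  out[center_idx(N, N0), center_idx(N, N0)] <- x
  out
}

#' Apply a function per channel of an N x N x L complex array
#' @keywords internal
map_channels <- function(a, f) {
  L <- dim(a)[3]
  out <- NULL
  for (l in seq_len(L)) {
    y <- f(a[, , l])
    if (is.null(out)) out <- array(0 + 0i, c(dim(y), L))
    out[, , l] <- y
  }
  out
}
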