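# Multicoil Cartesian k-space data model and noisy-acquisition simulation.
#
# Physical model: one phase-encode line (array row m) is acquired per TR and
# may be averaged w~_m times; averaging divides the per-sample complex noise
# variance sigma^2 by w~_m. Reducing the grid from N0 to N while keeping the
# readout duration fixed lowers the acquisition bandwidth, which is an
# additional SNR gain of N0/N, absorbed into "effective" averages
# w_m = w~_m * N0 / N.

#' Construct a multicoil k-space dataset
#'
#' @param s complex array `N0 x N0 x L` of noiseless k-space samples in
#'   centered order (phase encode along rows, readout along columns).
#' @param maps complex array `N0 x N0 x L` of coil sensitivity maps on the
#'   image grid.
#' @param fov_mm physical field of view in millimetres (square FOV); sets the
#'   k-space sample spacing 1/FOV.
#' @param id character label for the dataset.
#' @return object of class `kspace_dataset`
#' @export
kspace_dataset <- function(s, maps, fov_mm = 220, id = "dataset") {
  stopifnot(length(dim(s)) == 3L, length(dim(maps)) == 3L)
  if (!all(dim(s) == dim(maps)))
    stop("k-space and sensitivity maps must share dimensions")
  N0 <- dim(s)[1]
  if (dim(s)[2] != N0) stop("grid must be square")
  if (N0 %% 2L != 0L) stop("grid size must be even")
  structure(list(s = s, maps = maps, fov_mm = fov_mm, id = id,
                 N0 = N0, L = dim(s)[3]),
            class = "kspace_dataset")
}

#' @export
print.kspace_dataset <- function(x, ...) {
  cat(sprintf("<kspace_dataset '%s': %d x %d grid, %d channels, FOV %g mm>\n",
              x$id, x$N0, x$N0, x$L, x$fov_mm))
  invisible(x)
}

#' Noise model for unaveraged k-space samples
#'
#' Noise is i.i.d. circular complex Gaussian with zero mean and variance
#' `sigma^2` per sample, assumed prewhitened across channels (no interchannel
#' correlation). `seed` controls the master noise realization; the realization
#' for training dataset `t` is a deterministic function of `(seed, t)`.
#'
#' @param sigma standard deviation of one unaveraged complex noise sample
#'   (so `Var(Re) = Var(Im) = sigma^2 / 2`).
#' @param seed integer master seed.
#' @return object of class `noise_model`
#' @export
noise_model <- function(sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be nonnegative")
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_model")
}

# Deterministic sub-seed for dataset t, kept inside 32-bit integer range.
noise_subseed <- function(seed, t) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(t) * 7919) %% 2147483629)
}

#' Draw the master unit-variance noise realization for dataset t
#'
#' One realization lives on the full `N0` grid; candidate grid sizes crop it,
#' so the same underlying noise vector is shared across candidate `N` and the
#' outer grid search compares candidates on equal footing.
#'
#' @param noise a [noise_model()]
#' @param t dataset index
#' @param N0,L master grid size and channel count
#' @return complex array `N0 x N0 x L` with unit variance per entry
#' @export
master_noise <- function(noise, t, N0, L) {
  set.seed(noise_subseed(noise$seed, t))
  n <- N0 * N0 * L
  array(complex(real = stats::rnorm(n, sd = 1 / sqrt(2)),
                imaginary = stats::rnorm(n, sd = 1 / sqrt(2))),
        c(N0, N0, L))
}

#' Crop k-space to a centered lower-resolution grid
#'
#' Samples falling outside the centered `N x N` grid are discarded (not
#' filtered); this models acquiring fewer phase-encode lines and a narrower
#' readout window.
#'
#' @param ds a [kspace_dataset()] or a complex array `N0 x N0 x L`
#' @param N even target grid size, `2 <= N <= N0`
#' @return complex array `N x N x L`
#' @export
crop_kspace <- function(ds, N) {
  s <- if (inherits(ds, "kspace_dataset")) ds$s else ds
  N0 <- dim(s)[1]
  if (N %% 2L != 0L) stop("N must be even")
  if (N < 2L || N > N0) stop("N must satisfy 2 <= N <= N0")
  idx <- center_idx(N, N0)
  s[idx, idx, , drop = FALSE]
}

#' Convert actual averages to effective averages
#'
#' Effective averages absorb the bandwidth-related SNR gain of a reduced
#' readout: `w_m = w_actual_m * N0 / N`.
#'
#' @param w_actual positive per-line average counts (length `N`)
#' @param N,N0 acquisition and reference grid sizes
#' @return numeric vector of effective averages
#' @export
effective_averages <- function(w_actual, N, N0) {
  if (any(w_actual <= 0)) stop("average counts must be positive")
  w_actual * N0 / N
}

#' Convert effective averages back to actual averages
#'
#' Inverse of [effective_averages()].
#'
#' @inheritParams effective_averages
#' @param w effective averages (length `N`)
#' @export
actual_averages <- function(w, N, N0) {
  if (any(w <= 0)) stop("average counts must be positive")
  w * N / N0
}

#' Simulate an averaged, bandwidth-adjusted noisy acquisition
#'
#' Produces `d = s_N + z_N / sqrt(w)` per phase-encode line, where `z` is the
#' master unit-variance realization for `(seed, t)` on the `N0` grid scaled by
#' `sigma` and cropped to `N`. The per-line variance of `d - s` is exactly
#' `sigma^2 / w_m`.
#'
#' @param s_N complex array `N x N x L` of noiseless cropped k-space
#' @param pattern an [averaging_pattern()] with matching `N`
#' @param noise a [noise_model()]
#' @param t dataset index selecting the master noise realization
#' @param z optional precomputed master noise array (`N0 x N0 x L`) to avoid
#'   redrawing inside tight loops
#' @return object of class `noisy_acquisition` with fields `d`, `pattern`,
#'   `sigma`
#' @export
simulate_noisy_acquisition <- function(s_N, pattern, noise, t = 1L, z = NULL) {
  N <- dim(s_N)[1]
  L <- dim(s_N)[3]
  if (N != pattern$N) stop("s_N grid does not match pattern$N")
  if (is.null(z)) z <- master_noise(noise, t, pattern$N0, L)
  z_N <- crop_kspace(z, N)
  scale <- noise$sigma / sqrt(pattern$w)   # per line (rows)
  d <- s_N + array(scale, dim(s_N)) * z_N  # scale recycles down rows
  structure(list(d = d, pattern = pattern, sigma = noise$sigma),
            class = "noisy_acquisition")
}

#' Normalize a dataset so the peak voxel magnitude is one
#'
#' All channels are divided by one common scalar: the maximum magnitude over
#' voxels and channels of the per-channel inverse-Fourier images. After
#' normalization the multichannel images have voxel magnitudes in `[0, 1]`.
#'
#' @param ds a [kspace_dataset()]
#' @return normalized [kspace_dataset()]
#' @export
normalize_dataset <- function(ds) {
  imgs <- map_channels(ds$s, ift2c)
  peak <- max(abs(imgs))
  if (peak == 0) stop("cannot normalize an all-zero dataset")
  ds$s <- ds$s / peak
  ds
}

#' Total scan time of an averaging pattern, in TRs
#'
#' @param pattern an [averaging_pattern()] (uses the integer actual averages
#'   if present, otherwise converts the effective averages) or an
#'   `integer_pattern`
#' @return integer TR count `sum(w_actual)`
#' @export
scan_time <- function(pattern) {
  if (inherits(pattern, "integer_pattern")) return(sum(pattern$q))
  sum(actual_averages(pattern$w, pattern$N, pattern$N0))
}
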