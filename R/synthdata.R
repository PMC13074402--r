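# Synthetic multicoil brain-like phantoms with known sensitivities.
#
# The generator emulates the features of T1-weighted multicoil brain slices
# that matter for coverage/averaging design: piecewise-smooth anatomy with a
# few tissue classes, thin bright vascular-like curves (the fine structure
# whose loss is the cost of reduced resolution), a smooth complex phase,
# smooth coil sensitivities, and an SNR convention calibrated in a central
# white-matter ROI under the reference acquisition (N = N0 with uniform
# averaging).

#' Specification of the synthetic phantom suite
#'
#' Defaults are desk-scale: a 64-grid with 4 channels and 32 slices, chosen
#' so the full design pipeline (including the ADMM reconstructor) runs in
#' minutes on one CPU while preserving the structure of a full-scale study
#' (320-grid, 16 channels, thousands of slices).
#'
#' @param N0 master grid size (even)
#' @param L number of receiver channels (`L = 1` gives unit sensitivities)
#' @param T_sets number of phantom datasets
#' @param seed master generator seed
#' @param contrasts relative tissue intensities in `(0, 1]` for white matter,
#'   gray matter, and CSF
#' @param n_vessels vessels per phantom
#' @param vessel_width vessel radius range in voxels (>= 1 voxel wide)
#' @param sens_scale coil sensitivity smoothness scale, fraction of the FOV
#' @param fov_mm field of view in millimetres
#' @param w0 reference uniform averages of the scan-time budget
#' @param split train/validation/test proportions (sum to one)
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(N0 = 64L, L = 4L, T_sets = 32L, seed = 1L,
                         contrasts = c(wm = 0.9, gm = 0.6, csf = 0.3),
                         n_vessels = 6L, vessel_width = c(1, 2),
                         sens_scale = 0.6, fov_mm = 220, w0 = 8L,
                         split = c(train = 0.8, val = 0.1, test = 0.1)) {
  stopifnot(N0 %% 2L == 0L, L >= 1L, T_sets >= 1L,
            all(contrasts > 0), all(contrasts <= 1),
            all(vessel_width >= 0.5))
  structure(list(N0 = as.integer(N0), L = as.integer(L),
                 T_sets = as.integer(T_sets), seed = as.integer(seed),
                 contrasts = contrasts, n_vessels = n_vessels,
                 vessel_width = vessel_width, sens_scale = sens_scale,
                 fov_mm = fov_mm, w0 = w0, split = split),
            class = "phantom_spec")
}

phantom_subseed <- function(spec, t, salt = 0L) {
  as.integer((as.numeric(spec$seed) * 69061 + as.numeric(t) * 30011 +
                as.numeric(salt) * 104729) %% 2147483629)
}

# smooth random closed boundary radius as a function of angle
perturbed_radius <- function(theta, base, n_harm = 4, amp = 0.05) {
  r <- rep(base, length(theta))
  for (k in seq_len(n_harm)) {
    r <- r + base * amp / k *
      (stats::runif(1, -1, 1) * cos(k * theta) +
         stats::runif(1, -1, 1) * sin(k * theta))
  }
  r
}

#' Generate one brain-like complex phantom
#'
#' Piecewise-smooth nested anatomy (CSF rim and ventricles, cortical
#' gray-matter ribbon, white-matter interior), thin curvilinear bright
#' vessel-like structures, and a smooth low-order polynomial phase map.
#' Deterministic in `(spec$seed, t)`.
#'
#' @param spec a [phantom_spec()]
#' @param t dataset index
#' @return list with `image` (complex `N0 x N0`), `labels` (integer matrix:
#'   0 background, 1 CSF, 2 gray matter, 3 white matter, 4 vessel), and
#'   `roi` (logical white-matter calibration mask, a central disk inside the
#'   white-matter label)
#' @export
generate_phantom <- function(spec, t) {
  set.seed(phantom_subseed(spec, t))
  N0 <- spec$N0
  co <- seq(-1, 1, length.out = N0)
  X <- matrix(co, N0, N0)          # varies down rows
  Y <- matrix(co, N0, N0, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  # head boundary and nested tissue shells
  r_head <- matrix(perturbed_radius(TH, 0.85, amp = 0.04), N0, N0)
  r_brain <- 0.88 * r_head
  r_gm <- 0.76 * r_head
  labels <- matrix(0L, N0, N0)
  labels[R < r_head] <- 1L                       # CSF rim fills the head
  labels[R < r_brain] <- 2L                      # cortical gray matter
  labels[R < r_gm] <- 3L                         # white matter interior
  # lateral-ventricle-like CSF lobes near the center
  for (sgn in c(-1, 1)) {
    cx <- 0.05 + stats::runif(1, -0.03, 0.03)
    cy <- sgn * (0.16 + stats::runif(1, -0.03, 0.03))
    vx <- ((X - cx) / 0.22)^2 + ((Y - cy) / 0.09)^2 < 1
    labels[vx & labels == 3L] <- 1L
  }
  inten <- c(spec$contrasts[["csf"]], spec$contrasts[["gm"]],
             spec$contrasts[["wm"]])
  img <- matrix(0, N0, N0)
  for (k in 1:3) img[labels == k] <- inten[k]
  # slowly varying intensity shading (receive-independent tissue variation)
  img <- img * (1 + 0.08 * (X * stats::runif(1, -1, 1) +
                              Y * stats::runif(1, -1, 1)))
  # vessels: thin bright random-walk curves confined to the brain
  vx_steps <- 40
  for (v in seq_len(spec$n_vessels)) {
    p <- c(stats::runif(1, -0.4, 0.4), stats::runif(1, -0.4, 0.4))
    ang <- stats::runif(1, 0, 2 * pi)
    wdt <- stats::runif(1, spec$vessel_width[1], spec$vessel_width[2])
    for (s in seq_len(vx_steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.3)
      p <- p + 0.02 * c(cos(ang), sin(ang))
      ij <- round((p + 1) / 2 * (N0 - 1)) + 1
      if (any(ij < 1) || any(ij > N0)) break
      half <- max(0L, as.integer(round((wdt - 1) / 2)))
      rows <- pmax(1, ij[1] - half):pmin(N0, ij[1] + half)
      cols <- pmax(1, ij[2] - half):pmin(N0, ij[2] + half)
      inside <- labels[rows, cols] %in% c(2L, 3L)
      block <- labels[rows, cols]
      block[inside] <- 4L
      labels[rows, cols] <- block
      imgb <- img[rows, cols]
      imgb[inside] <- 1.0
      img[rows, cols] <- imgb
    }
  }
  # smooth low-order polynomial phase
  ph <- stats::runif(5, -1, 1)
  phase <- 0.8 * (ph[1] * X + ph[2] * Y + ph[3] * X * Y +
                    ph[4] * (X^2 - Y^2) + ph[5] * (X^2 + Y^2))
  image <- img * exp(1i * phase)
  # calibration ROI: central disk restricted to white matter, grown until it
  # holds enough voxels for a stable SNR estimate
  roi <- matrix(FALSE, N0, N0)
  for (rad in seq(0.1, 0.45, by = 0.05)) {
    roi <- (R < rad) & labels == 3L
    if (sum(roi) >= 16) break
  }
  if (!any(roi)) roi <- labels == 3L
  list(image = image, labels = labels, roi = roi)
}

#' Generate smooth complex coil sensitivity maps
#'
#' Gaussian-lobed magnitudes centered on virtual coils placed on a circle
#' just outside the FOV, with low-order polynomial phases. The summed
#' sensitivity energy is strictly positive everywhere. With `L = 1` the map
#' is identically one (single-coil degenerate mode).
#'
#' @param spec a [phantom_spec()]
#' @param t dataset index
#' @return complex array `N0 x N0 x L`
#' @export
generate_sensitivities <- function(spec, t) {
  N0 <- spec$N0; L <- spec$L
  if (L == 1L) return(array(1 + 0i, c(N0, N0, 1)))
  set.seed(phantom_subseed(spec, t, salt = 1L))
  co <- seq(-1, 1, length.out = N0)
  X <- matrix(co, N0, N0)
  Y <- matrix(co, N0, N0, byrow = TRUE)
  maps <- array(0 + 0i, c(N0, N0, L))
  for (l in seq_len(L)) {
    ang <- 2 * pi * (l - 1) / L + stats::runif(1, -0.2, 0.2)
    cx <- 1.15 * cos(ang); cy <- 1.15 * sin(ang)
    mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * spec$sens_scale^2))
    ph <- stats::runif(3, -0.5, 0.5)
    phase <- ph[1] + ph[2] * X + ph[3] * Y
    maps[, , l] <- mag * exp(1i * phase)
  }
  maps
}

#' Assemble a synthetic training set of k-space datasets
#'
#' Generates `T_sets` phantoms with matched sensitivities, forms multicoil
#' k-space by the unitary Fourier transform of each channel image, normalizes
#' every dataset to unit peak voxel magnitude, and partitions indices into
#' train/validation/test splits.
#'
#' @param spec a [phantom_spec()]
#' @return object of class `training_set`: datasets, calibration ROIs,
#'   split index lists, and the generating [phantom_spec()]
#' @export
assemble_training_set <- function(spec) {
  datasets <- vector("list", spec$T_sets)
  rois <- vector("list", spec$T_sets)
  for (t in seq_len(spec$T_sets)) {
    ph <- generate_phantom(spec, t)
    maps <- generate_sensitivities(spec, t)
    s <- array(0 + 0i, c(spec$N0, spec$N0, spec$L))
    for (l in seq_len(spec$L)) s[, , l] <- ft2c(maps[, , l] * ph$image)
    ds <- kspace_dataset(s, maps, fov_mm = spec$fov_mm,
                         id = sprintf("phantom-%03d", t))
    datasets[[t]] <- normalize_dataset(ds)
    rois[[t]] <- ph$roi
  }
  n_tr <- round(spec$split[[1]] * spec$T_sets)
  n_val <- round(spec$split[[2]] * spec$T_sets)
  idx <- seq_len(spec$T_sets)
  split <- list(train = idx[seq_len(n_tr)],
                val = idx[n_tr + seq_len(n_val)],
                test = idx[(n_tr + n_val + 1):spec$T_sets])
  structure(list(datasets = datasets, rois = rois, split = split,
                 N0 = spec$N0, L = spec$L, T_sets = spec$T_sets,
                 w0 = spec$w0, spec = spec, noise = NULL),
            class = "training_set")
}

#' Measure the ROI SNR of the reference acquisition at a given sigma
#'
#' SNR is defined on the conventional reconstruction (zero-padded inverse
#' Fourier transform plus SENSE coil combination) of the reference
#' acquisition: `N = N0` with uniform `w0`-fold averaging. The signal is the
#' mean magnitude of the noiseless reconstruction over the white-matter ROI;
#' the noise level is the standard deviation of the magnitude of noise-only
#' reconstructions, estimated by Monte Carlo over repeated realizations and
#' averaged over the ROI.
#'
#' @param train a `training_set`
#' @param sigma unaveraged noise standard deviation
#' @param n_draws Monte Carlo noise realizations
#' @param n_datasets representative datasets averaged over
#' @param seed RNG seed for the Monte Carlo draws
#' @return scalar SNR estimate
#' @export
measure_roi_snr <- function(train, sigma, n_draws = 100, n_datasets = 3,
                            seed = 99L) {
  stopifnot(sigma > 0)
  use <- train$split$train[seq_len(min(n_datasets, length(train$split$train)))]
  snrs <- vapply(use, function(t) {
    ds <- train$datasets[[t]]
    roi <- train$rois[[t]]
    if (sum(roi) < 2)
      warning("ROI has fewer than 2 voxels; SNR estimate is unreliable")
    clean <- coil_combine(map_channels(ds$s, ift2c), ds$maps)
    sig <- mean(abs(clean)[roi])
    w_eff <- train$w0   # N = N0: effective equals actual averages
    set.seed(seed + t)
    acc <- matrix(0, sum(roi), n_draws)
    for (k in seq_len(n_draws)) {
      nvec <- ds$N0 * ds$N0 * ds$L
      z <- array(complex(real = stats::rnorm(nvec, sd = 1 / sqrt(2)),
                         imaginary = stats::rnorm(nvec, sd = 1 / sqrt(2))),
                 dim(ds$s)) * (sigma / sqrt(w_eff))
      nimg <- coil_combine(map_channels(z, ift2c), ds$maps)
      acc[, k] <- abs(nimg)[roi]
    }
    noise_sd <- mean(apply(acc, 1, stats::sd))
    sig / noise_sd
  }, numeric(1))
  mean(snrs)
}

#' Calibrate the noise level to a target ROI SNR
#'
#' The noise measure of [measure_roi_snr()] is estimated from noise-only
#' realizations and is therefore exactly proportional to `sigma`, so the
#' calibration reduces to a single Monte Carlo estimate at a reference sigma
#' followed by linear rescaling: `sigma = sigma_ref * SNR(sigma_ref) /
#' target_snr`.
#'
#' @param train a `training_set`
#' @param target_snr desired ROI SNR (finite and positive; use `sigma = 0`
#'   directly for the noiseless case)
#' @param n_draws,n_datasets,seed Monte Carlo controls, see
#'   [measure_roi_snr()]
#' @return calibrated `sigma`
#' @export
calibrate_sigma <- function(train, target_snr, n_draws = 100, n_datasets = 3,
                            seed = 99L) {
  if (!is.finite(target_snr) || target_snr <= 0)
    stop("target_snr must be finite and positive (use sigma = 0 for noiseless)")
  snr_ref <- measure_roi_snr(train, sigma = 1, n_draws = n_draws,
                             n_datasets = n_datasets, seed = seed)
  snr_ref / target_snr
}

#' Attach a calibrated noise model to a training set
#'
#' @param train a `training_set`
#' @param target_snr target ROI SNR, or `NULL` with an explicit `sigma`
#' @param sigma explicit noise standard deviation (overrides calibration)
#' @param seed noise-model master seed
#' @param ... passed to [calibrate_sigma()]
#' @return the training set with its `noise` field set
#' @export
set_noise <- function(train, target_snr = NULL, sigma = NULL, seed = 1L, ...) {
  if (is.null(sigma)) {
    if (is.null(target_snr)) stop("give target_snr or sigma")
    sigma <- calibrate_sigma(train, target_snr, ...)
  }
  train$noise <- noise_model(sigma, seed)
  train
}
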