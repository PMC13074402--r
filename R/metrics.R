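# Image-quality metrics and evaluation reports.

#' Normalized root-mean-squared error
#'
#' Implements `||x - r||_2 / ||x||_2` on complex images. Note the denominator
#' is the norm of the *estimate* `x`; set `reference_norm = TRUE` for the
#' conventional variant normalized by `||r||_2`.
#'
#' @param x complex (or numeric) image
#' @param r reference image of the same shape
#' @param reference_norm normalize by the reference instead of the estimate
#' @return nonnegative scalar
#' @export
nrmse <- function(x, r, reference_norm = FALSE) {
  if (!all(dim(x) == dim(r))) stop("shape mismatch")
  den <- if (reference_norm) sqrt(sum(abs(r)^2)) else sqrt(sum(abs(x)^2))
  if (den == 0) stop("zero-norm normalizer in NRMSE")
  sqrt(sum(abs(x - r)^2)) / den
}

# separable "valid" convolution with a 1D kernel along rows then columns
conv2_valid_sep <- function(x, g) {
  k <- length(g)
  n1 <- nrow(x); n2 <- ncol(x)
  out1 <- matrix(0, n1 - k + 1, n2)
  for (i in seq_len(k))
    out1 <- out1 + g[i] * x[i:(n1 - k + i), , drop = FALSE]
  out <- matrix(0, n1 - k + 1, n2 - k + 1)
  for (j in seq_len(k))
    out <- out + g[j] * out1[, j:(n2 - k + j), drop = FALSE]
  out
}

#' Structural similarity index (SSIM)
#'
#' Standard windowed SSIM on magnitude images: 11 x 11 Gaussian window with
#' standard deviation 1.5, stability constants `K1 = 0.01`, `K2 = 0.03`, and
#' dynamic range equal to the maximum magnitude of the reference `r` (the
#' range convention makes the metric asymmetric in its arguments). The map is
#' averaged over the valid (fully-windowed) region.
#'
#' @param x image (complex allowed; magnitudes are compared)
#' @param r reference image
#' @param K1,K2 stability constants
#' @param win_size,win_sigma Gaussian window size and width
#' @return scalar in `[-1, 1]`
#' @export
ssim <- function(x, r, K1 = 0.01, K2 = 0.03, win_size = 11, win_sigma = 1.5) {
  if (!all(dim(x) == dim(r))) stop("shape mismatch")
  X <- abs(x); R <- abs(r)
  range_r <- max(R)
  if (range_r == 0) range_r <- 1
  C1 <- (K1 * range_r)^2
  C2 <- (K2 * range_r)^2
  half <- (win_size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * win_sigma^2))
  g <- g / sum(g)
  mu_x <- conv2_valid_sep(X, g)
  mu_r <- conv2_valid_sep(R, g)
  sxx <- conv2_valid_sep(X * X, g) - mu_x^2
  srr <- conv2_valid_sep(R * R, g) - mu_r^2
  sxr <- conv2_valid_sep(X * R, g) - mu_x * mu_r
  map <- ((2 * mu_x * mu_r + C1) * (2 * sxr + C2)) /
    ((mu_x^2 + mu_r^2 + C1) * (sxx + srr + C2))
  mean(map)
}

#' Evaluate a completed design on a data split
#'
#' Reconstructs every dataset in the chosen split with each candidate's
#' trained parameters and final averaging pattern, computes NRMSE and SSIM
#' against the high-resolution reference, and aggregates. The `1 - NRMSE`
#' convenience column follows the higher-is-better plotting convention.
#'
#' @param result a `design_result` from [outer_select_N()]
#' @param train the `training_set` used for the design
#' @param split which index split to evaluate (`"test"` by default)
#' @return object of class `eval_report`: list with `per_dataset` (rows for
#'   the selected design), `by_candidate` (mean metrics per candidate N), and
#'   scalar summaries
#' @export
evaluate_design <- function(result, train, split = "test") {
  idx <- train$split[[split]]
  if (length(idx) == 0) stop("empty evaluation split")
  refs_hi <- lapply(idx, function(t) make_reference(train$datasets[[t]], train$N0))
  eval_one <- function(rec, t, r_hi) {
    ds <- train$datasets[[t]]
    pat <- final_pattern(rec)
    s_N <- crop_kspace(ds, rec$N)
    acq <- simulate_noisy_acquisition(s_N, pat, train$noise, t)
    rc <- rec$recon
    rc$maps <- ds$maps   # maps are per-dataset side information
    x <- reconstruct(rc, acq)
    c(nrmse = nrmse(x, r_hi), ssim = ssim(x, r_hi))
  }
  by_cand <- do.call(rbind, lapply(result$records, function(rec) {
    m <- vapply(seq_along(idx),
                function(i) eval_one(rec, idx[i], refs_hi[[i]]), numeric(2))
    data.frame(N = rec$N, mean_nrmse = mean(m["nrmse", ]),
               one_minus_nrmse = 1 - mean(m["nrmse", ]),
               mean_ssim = mean(m["ssim", ]))
  }))
  best <- result$records[[which(vapply(result$records, `[[`, 0, "N") ==
                                  result$N_hat)[1]]]
  per <- do.call(rbind, lapply(seq_along(idx), function(i) {
    m <- eval_one(best, idx[i], refs_hi[[i]])
    data.frame(t = idx[i], N = best$N, nrmse = m["nrmse"], ssim = m["ssim"],
               row.names = NULL)
  }))
  structure(list(per_dataset = per, by_candidate = by_cand,
                 N_hat = result$N_hat,
                 mean_nrmse = mean(per$nrmse), mean_ssim = mean(per$ssim),
                 kind = result$kind, mode = result$mode),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s / %s averaging, N_hat = %d>\n",
              x$kind, x$mode, x$N_hat))
  cat(sprintf("  mean NRMSE %.4f | mean SSIM %.4f over %d datasets\n",
              x$mean_nrmse, x$mean_ssim, nrow(x$per_dataset)))
  invisible(x)
}

#' Write an evaluation report to JSON
#' @param report an `eval_report`
#' @param path output file
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#' @param path input file
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_dataset <- as.data.frame(x$per_dataset)
  x$by_candidate <- as.data.frame(x$by_candidate)
  structure(x, class = "eval_report")
}

#' Per-average SNR equivalence under square-root averaging gain
#'
#' Averaging `n` measurements scales SNR by `sqrt(n)`, so an acquisition with
#' per-average SNR `snr` and `n_avg` averages is equivalent to one with
#' `snr * sqrt(n_avg / n_avg_new)` per-average SNR and `n_avg_new` averages.
#' This makes design conclusions obtained at low SNR transferable to
#' higher-SNR regimes with fewer averages.
#'
#' @param snr per-average SNR of the reference experiment
#' @param n_avg averages in the reference experiment
#' @param n_avg_new averages in the rescaled experiment
#' @return equivalent per-average SNR
#' @export
equivalent_per_average_snr <- function(snr, n_avg, n_avg_new) {
  snr * sqrt(n_avg / n_avg_new)
}
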