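# Bilevel acquisition/reconstruction design.
#
# Inner problem (per candidate grid size N): jointly optimize the
# reconstruction parameters p and, in nonuniform mode, the effective
# averaging pattern w by (projected) minibatch stochastic gradient descent on
# the squared-error loss against matched-resolution references r^N. Outer
# problem: brute-force search over candidate N, scoring each trained design
# against the high-resolution references r^{N0} with the same noise
# realizations, and returning the argmin.

#' Squared-error training loss
#'
#' `J(x, r) = ||x - r||_2^2`, the sum over voxels of squared magnitudes of
#' the complex difference.
#'
#' @param x reconstructed image
#' @param r reference image, same shape
#' @return nonnegative scalar
#' @export
training_loss <- function(x, r) {
  if (!all(dim(x) == dim(r))) stop("shape mismatch")
  sum(abs(x - r)^2)
}

#' Noise-free reference image at resolution N
#'
#' Crops the dataset to the centered `N x N` grid, zero-pads back to `N0`,
#' applies the unitary inverse Fourier transform per channel, and combines
#' channels with the known sensitivities. `make_reference(ds, N0)` is the
#' high-resolution reference of the outer problem. References never depend
#' on the noise level or the averaging pattern.
#'
#' @param ds a [kspace_dataset()]
#' @param N reference resolution (even, `<= N0`)
#' @return complex `N0 x N0` image
#' @export
make_reference <- function(ds, N) {
  s_N <- crop_kspace(ds, N)
  coil_combine(zero_pad_recon(s_N, ds$N0), ds$maps)
}

#' Training schedule for the inner optimization
#'
#' Defaults depend on the reconstructor family and averaging mode and follow
#' the stochastic-gradient settings the design study uses at full scale:
#' SENSE-TV uniform trains the regularization parameter for 10 epochs at
#' learning rate 0.01 (decay 0.9); SENSE-TV nonuniform runs 45 joint epochs
#' (p: lr 0.001, decay 0.99; w: lr 0.01, decay 0.99) plus 5 refinement
#' epochs after rounding; apodized reconstruction trains the window with Adam
#' (lr 0.02, decay 0.99; the window's loss curvature spans orders of
#' magnitude between k-space center and edges, which a single SGD step size
#' cannot cover at small training-set sizes), 50 epochs in uniform mode and
#' 45 + 5 in nonuniform mode with lr 0.1 for w. Batch size 8 throughout; parameter gradients use the
#' mean-squared-error reduction (averaged over batch and voxels) and w
#' gradients are normalized to unit norm before the projected step.
#'
#' @param kind reconstructor family, `"apodized"` or `"sense_tv"`
#' @param mode `"uniform"` or `"nonuniform"`
#' @param ... overrides for any schedule field
#' @return object of class `inner_schedule`
#' @export
inner_schedule <- function(kind = c("apodized", "sense_tv"),
                           mode = c("uniform", "nonuniform"), ...) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  sched <- switch(paste(kind, mode),
    "sense_tv uniform" = list(epochs_joint = 10L, epochs_refine = 0L,
                              lr_p = 0.01, decay_p = 0.9,
                              lr_w = 0, decay_w = 1),
    "sense_tv nonuniform" = list(epochs_joint = 45L, epochs_refine = 5L,
                                 lr_p = 0.001, decay_p = 0.99,
                                 lr_w = 0.01, decay_w = 0.99),
    "apodized uniform" = list(epochs_joint = 50L, epochs_refine = 0L,
                              lr_p = 0.02, decay_p = 0.99,
                              lr_w = 0, decay_w = 1),
    "apodized nonuniform" = list(epochs_joint = 45L, epochs_refine = 5L,
                                 lr_p = 0.02, decay_p = 0.99,
                                 lr_w = 0.1, decay_w = 0.99))
  sched$batch_size <- 8L
  sched$redraw_noise <- FALSE
  # Adam for the window values: their loss curvature spans several orders of
  # magnitude between the k-space center and edges, so a per-entry adaptive
  # step is needed at small training-set sizes; SGD remains available.
  sched$optimizer_p <- if (kind == "apodized") "adam" else "sgd"
  over <- list(...)
  sched[names(over)] <- over
  structure(c(sched, list(kind = kind, mode = mode)),
            class = "inner_schedule")
}

sgd_subseed <- function(seed, epoch) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(epoch) * 16807) %%
               2147483629)
}

# loss and gradients for one sample, dispatched on the reconstructor family
sample_loss_grad <- function(recon, s_N, z_N, w, r, sigma) {
  if (inherits(recon, "recon_apodized"))
    apodized_loss_grad(recon, s_N, z_N, w, r, sigma)
  else if (inherits(recon, "recon_sense_tv"))
    sense_tv_loss_grad(recon, s_N, z_N, w, r, sigma)
  else stop("unsupported reconstructor for gradient training")
}

# sensitivity maps are data, not trainable parameters: reconstructing or
# differentiating on dataset t uses that dataset's maps
with_maps <- function(recon, maps) { recon$maps <- maps; recon }

# gradient step on the reconstruction parameters; opt carries Adam state
update_params <- function(recon, grads, lr, opt) {
  if (inherits(recon, "recon_apodized")) {
    g <- grads$grad_h
    if (opt$name == "adam") {
      opt$t <- opt$t + 1
      opt$m <- 0.9 * opt$m + 0.1 * g
      opt$v <- 0.999 * opt$v + 0.001 * g^2
      mhat <- opt$m / (1 - 0.9^opt$t)
      vhat <- opt$v / (1 - 0.999^opt$t)
      step <- lr * mhat / (sqrt(vhat) + 1e-8)
    } else {
      step <- lr * g
    }
    recon$h <- pmax(recon$h - step, recon$eps)
  } else {
    recon$log_lambda <- recon$log_lambda - lr * grads$grad_log_lambda
  }
  list(recon = recon, opt = opt)
}

# shared SGD engine for both averaging modes
run_inner_sgd <- function(recon, N, train, sched, seed, optimize_w) {
  if (!is.null(recon$N) && recon$N != N)
    stop("reconstructor was built for N = ", recon$N, ", not N = ", N)
  idx <- train$split$train
  if (length(idx) == 0) stop("empty training split")
  noise <- train$noise
  if (is.null(noise)) stop("training set has no noise model; call set_noise()")
  sigma <- noise$sigma
  N0 <- train$N0
  budget <- budget_effective(N, N0, train$w0)
  s_list <- lapply(idx, function(t) crop_kspace(train$datasets[[t]], N))
  r_list <- lapply(idx, function(t) make_reference(train$datasets[[t]], N))
  z_list <- lapply(idx, function(t) crop_kspace(
    master_noise(noise, t, N0, train$L), N))
  m_list <- lapply(idx, function(t) train$datasets[[t]]$maps)
  w <- uniform_pattern(N, N0, train$w0)$w
  lr_p <- sched$lr_p; lr_w <- sched$lr_w
  opt <- list(name = if (is.null(sched$optimizer_p)) "sgd" else
    sched$optimizer_p, m = 0, v = 0, t = 0)
  trace <- numeric(0)
  run_phase <- function(n_epochs, joint, recon, w, lr_p, lr_w, epoch0) {
    for (ep in seq_len(n_epochs)) {
      set.seed(sgd_subseed(seed, epoch0 + ep))
      ord <- sample(seq_along(idx))
      if (isTRUE(sched$redraw_noise)) {
        z_list <<- lapply(idx, function(t) crop_kspace(
          master_noise(noise_model(sigma, noise$seed + 1000L * (epoch0 + ep)),
                       t, N0, train$L), N))
      }
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / sched$batch_size))) {
        gp <- NULL; gw <- 0
        for (i in b) {
          g <- sample_loss_grad(with_maps(recon, m_list[[i]]), s_list[[i]],
                                z_list[[i]], w, r_list[[i]], sigma)
          losses <- c(losses, g$loss)
          if (is.null(gp)) gp <- g else {
            if (!is.null(g$grad_h)) gp$grad_h <- gp$grad_h + g$grad_h
            if (!is.null(g$grad_log_lambda))
              gp$grad_log_lambda <- gp$grad_log_lambda + g$grad_log_lambda
          }
          if (joint) gw <- gw + g$grad_w
        }
        # mean-squared-error reduction: the minibatch objective is averaged
        # over batch samples and voxels, which is what makes the stated
        # learning rates (e.g. lr = 1 for window values) well-scaled
        red <- length(b) * N0^2
        if (!is.null(gp$grad_h)) gp$grad_h <- gp$grad_h / red
        if (!is.null(gp$grad_log_lambda))
          gp$grad_log_lambda <- gp$grad_log_lambda / red
        up <- update_params(recon, gp, lr_p, opt)
        recon <- up$recon; opt <<- up$opt
        if (joint) {
          w <- project_to_budget(w - lr_w * normalize_gradient(gw), budget)
        }
      }
      trace <<- c(trace, mean(losses))
      lr_p <- lr_p * sched$decay_p
      lr_w <- lr_w * sched$decay_w
    }
    list(recon = recon, w = w, lr_p = lr_p, lr_w = lr_w)
  }
  if (optimize_w) {
    ph <- run_phase(sched$epochs_joint, joint = TRUE, recon, w, lr_p, lr_w, 0L)
    w_hat <- ph$w
    q_hat <- round_to_integer_averages(
      averaging_pattern(N, w_hat, N0, train$w0))
    frozen <- pattern_from_integer(q_hat)
    ph2 <- run_phase(sched$epochs_refine, joint = FALSE, ph$recon, frozen$w,
                     ph$lr_p, 0, sched$epochs_joint)
    list(recon = ph2$recon, w_hat = w_hat, q_hat = q_hat, pattern = frozen,
         trace = trace)
  } else {
    ph <- run_phase(sched$epochs_joint, joint = FALSE, recon, w, lr_p, 0, 0L)
    list(recon = ph$recon, w_hat = w, q_hat = NULL,
         pattern = averaging_pattern(N, w, N0, train$w0), trace = trace)
  }
}

#' Inner optimization with uniform averaging
#'
#' Fixes the averaging pattern at [uniform_pattern()] and trains the
#' reconstruction parameters by minibatch SGD on [training_loss()] against
#' the matched-resolution references `r^N`. Deterministic under a fixed seed
#' (data order and noise realizations).
#'
#' @param recon initial reconstructor
#' @param N candidate grid size
#' @param train a `training_set` with a noise model attached
#' @param sched an [inner_schedule()]
#' @param seed run seed controlling minibatch shuffling
#' @return list with trained `recon`, final `pattern`, and the per-epoch
#'   mean-loss `trace`
#' @export
inner_optimize_uniform <- function(recon, N, train,
                                   sched = inner_schedule(recon$kind, "uniform"),
                                   seed = 1L) {
  run_inner_sgd(recon, N, train, sched, seed, optimize_w = FALSE)
}

#' Joint inner optimization of parameters and averaging pattern
#'
#' Initializes `w` at [uniform_pattern()], then alternates minibatch updates:
#' the reconstruction parameters move by SGD while `w` takes a projected
#' normalized-gradient step onto the scan-time budget. After the joint
#' epochs, `w` is rounded to integer actual averages
#' ([round_to_integer_averages()]), frozen, and the parameters are refined
#' for the remaining epochs.
#'
#' @inheritParams inner_optimize_uniform
#' @return list with trained `recon`, the continuous `w_hat`, the rounded
#'   `q_hat`, the frozen final `pattern`, and the loss `trace`
#' @export
inner_optimize_nonuniform <- function(recon, N, train,
                                      sched = inner_schedule(recon$kind,
                                                             "nonuniform"),
                                      seed = 1L) {
  run_inner_sgd(recon, N, train, sched, seed, optimize_w = TRUE)
}

final_pattern <- function(record) record$pattern

# default initial reconstructor per family
init_recon <- function(kind, N, N0, maps, lambda_init = 1e-2, rho = 0.1,
                       iterations = 50L) {
  if (kind == "apodized") recon_apodized(N, N0, maps)
  else recon_sense_tv(lambda_init, maps, N, N0, rho = rho,
                      iterations = iterations)
}

#' Outer brute-force selection of the acquisition grid size
#'
#' For every candidate `N`, runs the inner optimization (uniform or
#' nonuniform averaging) against the matched-resolution references, then
#' scores the trained design by the summed loss of its reconstructions
#' against the *high-resolution* references `r^{N0}` over the training
#' datasets, reusing the same master noise realizations. Returns the
#' candidate attaining the lowest outer loss together with the full
#' per-candidate records.
#'
#' @param train a `training_set` with a noise model attached
#' @param kind reconstructor family (`"apodized"` or `"sense_tv"`)
#' @param mode averaging mode (`"uniform"` or `"nonuniform"`)
#' @param candidates even candidate grid sizes; defaults to 30% to 100% of
#'   `N0` in 10% steps (rounded to even)
#' @param sched optional [inner_schedule()] override
#' @param seed run seed
#' @param lambda_init initial TV regularization parameter (SENSE-TV)
#' @param tune_rho tune the ADMM penalty per candidate on a representative
#'   slice before training (SENSE-TV)
#' @param iterations ADMM iteration count (SENSE-TV)
#' @return object of class `design_result`
#' @export
outer_select_N <- function(train, kind = c("apodized", "sense_tv"),
                           mode = c("uniform", "nonuniform"),
                           candidates = NULL, sched = NULL, seed = 1L,
                           lambda_init = 1e-2, tune_rho = TRUE,
                           iterations = 50L) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  N0 <- train$N0
  if (is.null(candidates))
    candidates <- unique(pmax(2, 2 * round(seq(0.3, 1, by = 0.1) * N0 / 2)))
  if (length(candidates) == 0) stop("empty candidate set")
  if (is.null(sched)) sched <- inner_schedule(kind, mode)
  noise <- train$noise
  if (is.null(noise)) stop("training set has no noise model; call set_noise()")
  idx <- train$split$train
  refs_hi <- lapply(idx, function(t) make_reference(train$datasets[[t]], N0))
  records <- lapply(candidates, function(N) {
    maps1 <- train$datasets[[idx[1]]]$maps
    recon <- init_recon(kind, N, N0, maps1, lambda_init,
                        iterations = iterations)
    if (kind == "sense_tv" && tune_rho) {
      pat <- uniform_pattern(N, N0, train$w0)
      acq <- simulate_noisy_acquisition(crop_kspace(train$datasets[[idx[1]]], N),
                                        pat, noise, idx[1])
      r1 <- make_reference(train$datasets[[idx[1]]], N)
      recon <- tune_admm_rho(recon, acq, r1)
      # coarse initialization of the TV weight on the same representative
      # slice; SGD then fine-tunes log(lambda)
      lam_grid <- 10^seq(-4, 1, by = 0.5)
      errs <- vapply(lam_grid, function(lam) {
        rc <- recon; rc$log_lambda <- log(lam)
        nrmse(reconstruct(rc, acq), r1)
      }, numeric(1))
      recon$log_lambda <- log(lam_grid[which.min(errs)])
    }
    fit <- if (mode == "uniform")
      inner_optimize_uniform(recon, N, train, sched, seed)
    else inner_optimize_nonuniform(recon, N, train, sched, seed)
    outer_loss <- design_outer_loss(fit$recon, fit$pattern, train, idx,
                                    refs_hi)
    c(fit, list(N = N, outer_loss = outer_loss))
  })
  losses <- vapply(records, `[[`, 0, "outer_loss")
  structure(list(N_hat = candidates[which.min(losses)],
                 records = records, candidates = candidates,
                 outer_losses = losses, kind = kind, mode = mode,
                 seed = seed, N0 = N0, w0 = train$w0,
                 sigma = noise$sigma),
            class = "design_result")
}

#' Outer loss of a trained design against high-resolution references
#'
#' Recomputes the summed squared-error loss of the design's reconstructions
#' against `r^{N0}` over the given datasets with the stored noise
#' realizations. Used both by the outer search and as an independent replay
#' of recorded losses.
#'
#' @param recon trained reconstructor
#' @param pattern final averaging pattern
#' @param train a `training_set`
#' @param idx dataset indices to sum over (default: training split)
#' @param refs_hi optional precomputed high-resolution references
#' @return scalar summed loss
#' @export
design_outer_loss <- function(recon, pattern, train, idx = train$split$train,
                              refs_hi = NULL) {
  if (is.null(refs_hi))
    refs_hi <- lapply(idx, function(t) make_reference(train$datasets[[t]],
                                                      train$N0))
  tot <- 0
  for (i in seq_along(idx)) {
    t <- idx[i]
    s_N <- crop_kspace(train$datasets[[t]], pattern$N)
    acq <- simulate_noisy_acquisition(s_N, pattern, train$noise, t)
    x <- reconstruct(with_maps(recon, train$datasets[[t]]$maps), acq)
    tot <- tot + training_loss(x, refs_hi[[i]])
  }
  tot
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result: %s / %s averaging>\n", x$kind, x$mode))
  cat(sprintf("  candidates N = {%s}\n", paste(x$candidates, collapse = ", ")))
  cat(sprintf("  selected N_hat = %d (outer losses: %s)\n", x$N_hat,
              paste(signif(x$outer_losses, 4), collapse = ", ")))
  invisible(x)
}
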