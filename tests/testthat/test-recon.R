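test_that("forward model reduces to the unitary Fourier transform", {
  set.seed(20)
  N0 <- 8
  maps1 <- array(1 + 0i, c(N0, N0, 1))
  x <- rand_cx_mat(N0)
  E <- forward_model_apply(x, maps1, N0)
  expect_equal(E[, , 1], ft2c(x), tolerance = 1e-12)
  expect_equal(forward_model_apply(x * 0, maps1, N0)[, , 1],
               matrix(0 + 0i, N0, N0))
})

test_that("forward model and adjoint satisfy the inner-product identity", {
  set.seed(21)
  N0 <- 10; N <- 6; L <- 3
  maps <- rand_cx_cube(N0, L)
  for (k in 1:5) {
    x <- rand_cx_mat(N0)
    y <- rand_cx_cube(N, L)
    lhs <- sum(Conj(forward_model_apply(x, maps, N)) * y)
    rhs <- sum(Conj(x) * forward_model_adjoint(y, maps))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("finite differences vanish on constants and count periodic edges", {
  expect_equal(finite_difference_apply(matrix(3 + 2i, 5, 5)),
               array(0 + 0i, c(5, 5, 2)))
  # 1D step of height 1: the jump and the periodic wrap each contribute 1
  step <- matrix(c(0, 0, 0, 1, 1, 1) + 0i, 6, 1)
  expect_equal(sum(abs(finite_difference_apply(step))), 2)
  set.seed(22)
  a <- rand_cx_mat(6); b <- rand_cx_mat(6)
  expect_equal(finite_difference_apply(a + 2 * b),
               finite_difference_apply(a) + 2 * finite_difference_apply(b),
               tolerance = 1e-12)
})

test_that("zero-padded reconstruction obeys Fourier identities", {
  set.seed(23)
  d <- rand_cx_cube(8, 2)
  # N = N0: plain inverse transform
  f <- zero_pad_recon(d, 8)
  expect_equal(f[, , 1], ift2c(d[, , 1]), tolerance = 1e-12)
  # a unit sample at the k-space center gives a flat image
  dc <- array(0 + 0i, c(4, 4, 1)); dc[3, 3, 1] <- 1
  img <- zero_pad_recon(dc, 8)[, , 1]
  expect_equal(max(abs(img - img[1, 1])), 0, tolerance = 1e-12)
  # Parseval under the unitary convention
  expect_equal(sum(abs(zero_pad_recon(d, 16))^2), sum(abs(d)^2),
               tolerance = 1e-10)
})

test_that("coil combination is unit-gain on consistent channels", {
  set.seed(24)
  N0 <- 8; L <- 3
  maps1 <- array(1 + 0i, c(N0, N0, 1))
  f <- rand_cx_cube(N0, 1)
  expect_equal(coil_combine(f, maps1), f[, , 1], tolerance = 1e-12)
  maps <- rand_cx_cube(N0, L)
  x <- rand_cx_mat(N0)
  fl <- array(0 + 0i, c(N0, N0, L))
  for (l in 1:L) fl[, , l] <- maps[, , l] * x
  expect_equal(coil_combine(fl, maps), x, tolerance = 1e-10)
  # direct evaluation of the formula on random inputs
  g <- rand_cx_cube(N0, L)
  num <- matrix(0 + 0i, N0, N0); den <- matrix(0, N0, N0)
  for (l in 1:L) {
    num <- num + Conj(maps[, , l]) * g[, , l]
    den <- den + abs(maps[, , l])^2
  }
  expect_equal(coil_combine(g, maps), num / den, tolerance = 1e-12)
})

test_that("flat-window apodized recon is identical to plain zero-pad recon", {
  set.seed(25)
  N0 <- 8; N <- 6; L <- 2
  maps <- rand_cx_cube(N0, L)
  d <- rand_cx_cube(N, L)
  rec <- recon_apodized(N, N0, maps)
  acq <- list(d = d)
  expect_identical(reconstruct(rec, acq),
                   coil_combine(zero_pad_recon(d, N0), maps))
  # near-zero window annihilates the image
  rec0 <- recon_apodized(N, N0, maps, h = matrix(1e-12, N, N), eps = 1e-12)
  expect_lt(max(abs(reconstruct(rec0, acq))), 1e-10)
})

test_that("apodized recon equals image-domain convolution with the window PSF", {
  set.seed(26)
  N <- 8
  maps1 <- array(1 + 0i, c(N, N, 1))
  d <- rand_cx_cube(N, 1)
  h <- matrix(runif(N * N, 0.2, 1.5), N, N)
  rec <- recon_apodized(N, N, maps1, h = h)
  x_win <- reconstruct(rec, list(d = d))
  plain <- ift2c(d[, , 1])
  psf <- ift2c(h + 0i)
  x_conv <- conv_circ_direct(plain, psf, offset = N / 2) / N
  expect_equal(x_win, x_conv, tolerance = 1e-10)
})

test_that("apodized recon is linear in the data; SENSE-TV is not", {
  set.seed(27)
  N0 <- 12; N <- 8; L <- 2
  tr <- tiny_training_set(N0 = N0, L = L, T_sets = 1, seed = 41)
  maps <- tr$datasets[[1]]$maps
  d1 <- rand_cx_cube(N, L); d2 <- rand_cx_cube(N, L)
  rec <- recon_apodized(N, N0, maps, h = matrix(runif(N^2, .5, 1), N, N))
  lin <- reconstruct(rec, list(d = d1 + 2 * d2))
  expect_equal(lin, reconstruct(rec, list(d = d1)) +
                 2 * reconstruct(rec, list(d = d2)), tolerance = 1e-10)
  w <- rep(3, N)
  rtv <- recon_sense_tv(0.5, maps, N, N0, rho = 0.3, iterations = 15)
  xa <- sense_tv_solve(rtv, d1, w)$x
  xb <- sense_tv_solve(rtv, d2, w)$x
  xab <- sense_tv_solve(rtv, d1 + d2, w)$x
  expect_gt(max(abs(xab - xa - xb)), 1e-4)
})

test_that("SENSE-TV with vanishing lambda matches the least-squares recon", {
  set.seed(28)
  N0 <- 10
  maps1 <- array(1 + 0i, c(N0, N0, 1))
  x0 <- rand_cx_mat(N0)
  d <- array(0 + 0i, c(N0, N0, 1)); d[, , 1] <- ft2c(x0)
  rec <- recon_sense_tv(1e-12, maps1, N0, N0, rho = 1, iterations = 30,
                        cg_iters = 30)
  x <- sense_tv_solve(rec, d, rep(1, N0))$x
  expect_equal(x, x0, tolerance = 1e-3)
})

test_that("total variation of the SENSE-TV solution is non-increasing in lambda", {
  set.seed(29)
  tr <- tiny_training_set(N0 = 16, L = 2, T_sets = 1, seed = 13)
  ds <- tr$datasets[[1]]
  N <- 12
  pat <- uniform_pattern(N, 16, 4)
  acq <- simulate_noisy_acquisition(crop_kspace(ds, N), pat,
                                    noise_model(0.2, 3), 1)
  tvs <- vapply(10^seq(-3, 1, by = 1), function(lam) {
    rec <- recon_sense_tv(lam, ds$maps, N, 16, rho = 0.2, iterations = 40,
                          cg_iters = 20)
    sum(abs(finite_difference_apply(sense_tv_solve(rec, acq$d, pat$w)$x)))
  }, numeric(1))
  expect_true(all(diff(tvs) <= 1e-8))
})

test_that("all reconstructors output the N0 grid regardless of N", {
  set.seed(30)
  tr <- tiny_training_set(N0 = 16, L = 2, T_sets = 1, seed = 14)
  ds <- tr$datasets[[1]]
  for (N in c(8, 12, 16)) {
    pat <- uniform_pattern(N, 16, 4)
    acq <- simulate_noisy_acquisition(crop_kspace(ds, N), pat,
                                      noise_model(0.1, 2), 1)
    xa <- reconstruct(recon_apodized(N, 16, ds$maps), acq)
    xt <- reconstruct(recon_sense_tv(0.01, ds$maps, N, 16, iterations = 5),
                      acq)
    expect_identical(dim(xa), c(16L, 16L))
    expect_identical(dim(xt), c(16L, 16L))
  }
})

test_that("the CNN plugin stub reproduces coil combination deterministically", {
  set.seed(31)
  tr <- tiny_training_set(N0 = 8, L = 2, T_sets = 1, seed = 15)
  ds <- tr$datasets[[1]]
  N <- 6
  pat <- uniform_pattern(N, 8, 2)
  acq <- simulate_noisy_acquisition(crop_kspace(ds, N), pat,
                                    noise_model(0.1, 7), 1)
  rec <- recon_cnn(cnn_identity_stub(ds$maps), weights = NULL, ds$maps, N, 8)
  x1 <- reconstruct(rec, acq)
  expect_equal(x1, coil_combine(zero_pad_recon(acq$d, 8), ds$maps),
               tolerance = 1e-12)
  expect_identical(x1, reconstruct(rec, acq))
})
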