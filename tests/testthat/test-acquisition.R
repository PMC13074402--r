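test_that("crop_kspace keeps the centered subgrid and discards the rest", {
  set.seed(1)
  s <- rand_cx_cube(8, 2)
  expect_identical(crop_kspace(s, 8), s)
  # centered convention: for N0 = 4, N = 2 the kept indices are rows/cols 2:3
  s4 <- array(complex(real = 1:32, imaginary = 0), c(4, 4, 2))
  expect_identical(crop_kspace(s4, 2), s4[2:3, 2:3, , drop = FALSE])
  # energy can only decrease, with equality iff the discarded rim is zero
  e_in <- sum(abs(s)^2)
  e_out <- sum(abs(crop_kspace(s, 4))^2)
  expect_lt(e_out, e_in)
  s_zero_rim <- array(0 + 0i, dim(s))
  s_zero_rim[3:6, 3:6, ] <- s[3:6, 3:6, ]
  expect_equal(sum(abs(crop_kspace(s_zero_rim, 4))^2),
               sum(abs(s_zero_rim)^2))
  expect_error(crop_kspace(s, 3), "even")
  expect_error(crop_kspace(s, 10), "2 <= N <= N0")
})

test_that("effective averages absorb the bandwidth factor N0/N", {
  expect_equal(effective_averages(rep(8, 4), 4, 4), rep(8, 4))
  expect_equal(effective_averages(2, 160, 320), 4)
  set.seed(2)
  w <- runif(6, 0.5, 10)
  expect_equal(actual_averages(effective_averages(w, 6, 24), 6, 24), w)
  expect_error(effective_averages(c(1, -1), 2, 4), "positive")
})

test_that("noisy acquisition has exact per-line variance sigma^2 / w_m", {
  N0 <- 8; N <- 4; L <- 2
  s_N <- array(0 + 0i, c(N, N, L))
  w <- c(2, 4, 8, 16)
  pat <- averaging_pattern(N, w, N0, w0 = sum(w * N / N0) / N0)
  nm <- noise_model(0.7, seed = 5)
  draws <- 3000
  ss <- matrix(0, N, draws)
  for (k in seq_len(draws)) {
    acq <- simulate_noisy_acquisition(s_N, pat, nm, t = k)
    ss[, k] <- apply(abs(acq$d)^2, 1, mean)
  }
  emp_var <- rowMeans(ss)
  expect_equal(emp_var, 0.7^2 / w, tolerance = 0.05)
  # doubling w halves the variance
  pat2 <- averaging_pattern(N, 2 * w, N0, pat$w0 * 2)
  ss2 <- matrix(0, N, draws)
  for (k in seq_len(draws)) {
    acq <- simulate_noisy_acquisition(s_N, pat2, nm, t = k)
    ss2[, k] <- apply(abs(acq$d)^2, 1, mean)
  }
  expect_equal(rowMeans(ss2) / emp_var, rep(0.5, N), tolerance = 0.07)
})

test_that("zero noise returns the data unchanged and draws are deterministic", {
  set.seed(3)
  s_N <- rand_cx_cube(4, 2)
  pat <- uniform_pattern(4, 8, 2)
  acq0 <- simulate_noisy_acquisition(s_N, pat, noise_model(0, 1), t = 1)
  expect_identical(acq0$d, s_N)
  nm <- noise_model(0.3, seed = 11)
  a1 <- simulate_noisy_acquisition(s_N, pat, nm, t = 4)
  a2 <- simulate_noisy_acquisition(s_N, pat, nm, t = 4)
  expect_identical(a1$d, a2$d)
  a3 <- simulate_noisy_acquisition(s_N, pat, nm, t = 5)
  expect_false(identical(a1$d, a3$d))
})

test_that("the same master realization is shared across candidate N", {
  set.seed(4)
  N0 <- 8; L <- 2
  s <- rand_cx_cube(N0, L)
  nm <- noise_model(0.5, seed = 9)
  w0 <- 4
  pat_full <- uniform_pattern(N0, N0, w0)
  pat_low <- uniform_pattern(4, N0, w0)
  a_full <- simulate_noisy_acquisition(s, pat_full, nm, t = 2)
  a_low <- simulate_noisy_acquisition(crop_kspace(s, 4), pat_low, nm, t = 2)
  z_full <- (a_full$d - s) * sqrt(pat_full$w[1]) / nm$sigma
  z_low <- (a_low$d - crop_kspace(s, 4)) * sqrt(pat_low$w[1]) / nm$sigma
  expect_equal(crop_kspace(z_full, 4), z_low, tolerance = 1e-12)
})

test_that("noise is white across channels and readout within a line", {
  N <- 4; L <- 2
  s_N <- array(0 + 0i, c(N, N, L))
  pat <- uniform_pattern(N, N, 1)
  nm <- noise_model(1, seed = 21)
  draws <- 2000
  v1 <- complex(length.out = draws); v2 <- v1; v3 <- v1
  for (k in seq_len(draws)) {
    d <- simulate_noisy_acquisition(s_N, pat, nm, t = k)$d
    v1[k] <- d[1, 1, 1]; v2[k] <- d[1, 2, 1]; v3[k] <- d[1, 1, 2]
  }
  cor_ro <- abs(mean(v1 * Conj(v2)))
  cor_ch <- abs(mean(v1 * Conj(v3)))
  expect_lt(cor_ro, 4 / sqrt(draws))
  expect_lt(cor_ch, 4 / sqrt(draws))
})

test_that("normalization scales all channels by one factor to unit peak", {
  tr <- tiny_training_set(N0 = 8, L = 2, T_sets = 1, seed = 3)
  ds <- tr$datasets[[1]]
  imgs <- sapply(seq_len(ds$L), function(l) max(abs(ift2c(ds$s[, , l]))))
  expect_equal(max(imgs), 1, tolerance = 1e-12)
  # idempotent and scale invariant
  ds2 <- normalize_dataset(ds)
  expect_equal(ds2$s, ds$s, tolerance = 1e-12)
  ds5 <- ds; ds5$s <- 5 * ds5$s
  expect_equal(normalize_dataset(ds5)$s, ds$s, tolerance = 1e-12)
  ds0 <- ds; ds0$s[] <- 0
  expect_error(normalize_dataset(ds0), "all-zero")
})

test_that("scan time counts TRs and matches the budget for uniform patterns", {
  expect_equal(scan_time(uniform_pattern(320, 320, 8)), 2560)
  for (N in c(80, 160, 320)) {
    q <- round_to_integer_averages(uniform_pattern(N, 320, 8))
    expect_identical(sum(q$q), 2560L)
  }
  set.seed(6)
  q <- structure(list(q = sample(0:5, 10, replace = TRUE), N = 10, N0 = 20,
                      w0 = 2), class = "integer_pattern")
  expect_equal(scan_time(q), sum(q$q))
})
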