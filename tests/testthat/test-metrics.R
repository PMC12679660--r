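test_that("Gaussian mutual information matches its closed form and symmetry", {
  expect_equal(mutual_information(0), 0)
  expect_equal(mutual_information(0.5), -0.5 * log2(0.75))
  expect_equal(mutual_information(0.5), mutual_information(-0.5))
  expect_true(all(diff(mutual_information(seq(0, 0.99, 0.01))) > 0))
  expect_warning(out <- mutual_information(1), "infinite")
  expect_identical(out, Inf)
  expect_error(mutual_information(1.01), "invalid-input")
  expect_error(mutual_information(NA), "invalid-input")
})

test_that("analytic mutual information agrees with a histogram estimator", {
  n <- 2e5
  for (r in c(0.3, 0.6, 0.9)) {
    set.seed(100 + round(100 * r))
    x <- rnorm(n)
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    expect_lt(abs(mutual_information(r) - hist_mi(x, y)), 0.05)
  }
})

test_that("eigenmode analysis of synthetic fields behaves as expected", {
  s <- sin(2 * pi * seq_len(400) / 25)
  em <- eigenmode_decomposition(cbind(s, s, s, s))
  expect_equal(em$explained_variance[1], 1)
  expect_lt(diff(range(abs(em$components[, 1]))), 1e-9)
  expect_equal(em$zero_lag_index[1], 1)

  ap <- make_fixture("antiphase-pair", steps = 600)
  em2 <- eigenmode_decomposition(ap)
  expect_lt(prod(em2$components[, 1]), 0)   # opposite-sign loadings

  expect_error(eigenmode_decomposition(matrix(1, 50, 3)),
               "degenerate-variance")
})

test_that("retained eigenmodes reconstruct the centered record", {
  set.seed(9)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(rnorm(36), 6, 6)
  em <- eigenmode_decomposition(X, n_components = 6)
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(eigenmode_reconstruct(em) - Xc)), 1e-9)
  expect_lt(max(abs(crossprod(em$components) - diag(6))), 1e-9)
  expect_true(all(diff(em$explained_variance) <= 1e-12))
  expect_lte(sum(em$explained_variance), 1 + 1e-12)
})

test_that("zero-lag synchrony index separates synchronous from unrelated channels", {
  sp <- make_fixture("synchronous-pair", steps = 800)
  expect_equal(zero_lag_synchrony(sp), 1)
  set.seed(5)
  noise <- matrix(rnorm(3000 * 8), 3000, 8)
  expect_lt(zero_lag_synchrony(noise), 0.25)
})

test_that("flux free energy vanishes exactly for identical exchanges", {
  s <- sin(2 * pi * seq_len(500) / 20) + 0.1 * cos(seq_len(500))
  rec <- make_flux_record(s, s)
  fs <- flux_free_energy(rec, lag_range = 5)
  expect_equal(fs$F, 0)
  expect_equal(fs$eq8_residual, 0)
  expect_equal(fs$A, 1)    # fractional scale
  fr <- flux_free_energy(rec, lag_range = 5, normalized = FALSE)
  expect_equal(fr$F, 0, tolerance = 1e-12)
  expect_gt(fr$A, 0)
})

test_that("independent flux noise carries no cross-correlation", {
  set.seed(11)
  rec <- make_flux_record(rnorm(2e4), rnorm(2e4))
  fs <- flux_free_energy(rec, lag_range = 5, normalized = FALSE)
  expect_lt(abs(fs$C) / fs$A, 0.05)
  expect_equal(fs$F, fs$A - fs$C)
  expect_error(flux_free_energy(rec, lag_range = 3e4),
               "insufficient-data")
})

test_that("free-energy trajectory differencing and stability classes", {
  tr <- free_energy_trajectory(c(4, 2, 1, 0.5))
  expect_true(all(tr$dF < 0))
  expect_true(all(tr$d2F > 0))
  expect_identical(tr$stability_class, "stable")   # F not yet near zero

  expect_identical(free_energy_trajectory(rep(2, 5))$stability_class,
                   "stable")
  # near-zero F with positive curvature: the unstable fixed point
  un <- free_energy_trajectory(c(10, 4, 1, 0.2, 0.05, 0.3))
  expect_identical(un$stability_class, "unstable")
  expect_error(free_energy_trajectory(c(1, 2)), "insufficient-windows")
})

test_that("channel capacity follows the Shannon form and state counts", {
  expect_equal(channel_capacity(7, C = 0, A = 3)$D, 0)
  expect_equal(channel_capacity(10, C = 1, A = 1)$D, 10)
  expect_equal(channel_capacity(1000, C = 2, A = 2)$D, 1000)
  expect_equal(channel_capacity(4, C = 3, A = 1)$D, 8)
  cp <- channel_capacity(8, C = 3, A = 1, n_neo = 6, n_limb = 2)
  expect_equal(cp$states_per_limbic, 16)
  expect_equal(channel_capacity(20, 1, 1)$states_mirror, 2^10)
  big <- channel_capacity(200, 1, 1)
  expect_true(is.na(big$states_mirror))
  expect_equal(big$log2_states_mirror, 100)
  expect_error(channel_capacity(4, 1, 0), "undefined-ratio")
  expect_error(channel_capacity(4, 1, 1, n_neo = 2, n_limb = 2),
               "n_neo")
  # D increases with C/A and is linear in n
  expect_true(all(diff(sapply(1:5, function(k)
    channel_capacity(8, k, 2)$D)) > 0))
  expect_equal(channel_capacity(16, 1, 2)$D, 2 * channel_capacity(8, 1, 2)$D)
})

test_that("prediction-error residuals satisfy their exact limits", {
  f <- small_field()
  z <- matrix(0, 300, 16)
  rb <- simulate_field(f, 300, drive = z, plasticity = list(enabled = FALSE))
  pe0 <- prediction_error_residual(rb, rb)
  expect_true(all(pe0$residual_norm == 0))

  f0 <- f
  f0$gains$g[] <- 0
  d <- white_noise_drive(16, 300, 0.2, seed = 8)
  rd <- simulate_field(f0, 300, drive = d, plasticity = list(enabled = FALSE))
  rz <- simulate_field(f0, 300, drive = z, plasticity = list(enabled = FALSE))
  pe <- prediction_error_residual(rd, rz)
  expect_equal(pe$residual_norm, sqrt(rowSums(d^2)))
  expect_true(all(pe$delta_minus == 0))

  f2 <- build_field(list(n = 12, seed = 2))
  r2 <- simulate_field(f2, 300, drive = matrix(0, 300, 12),
                       plasticity = list(enabled = FALSE))
  expect_error(prediction_error_residual(rd, r2), "incompatible-records")
})

test_that("windowed free energy is finite and on the fractional scale", {
  f <- small_field()
  d <- white_noise_drive(16, 1200, 0.2, seed = 4)
  rec <- simulate_field(f, 1200, drive = d)
  wf <- windowed_free_energy(rec, n_windows = 3)
  expect_equal(nrow(wf), 3)
  expect_true(all(is.finite(wf$F)))
  expect_true(all(wf$F >= 0 & wf$F <= 2))
  expect_true(all(wf$eq8_residual >= 0))
})
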