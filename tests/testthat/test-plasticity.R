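make_gain_state <- function(n = 4, g0 = 0.1, ei = NULL) {
  mask <- matrix(TRUE, n, n)
  diag(mask) <- FALSE
  if (is.null(ei)) ei <- rep(c("E", "I"), c(n - 1, 1))
  sgn <- matrix(rep(ifelse(ei == "E", 1, -1), each = n), n, n)
  g <- structure(list(eps = 1 * mask, g = g0 * mask, rho = 1 * mask,
                      sign = sgn, mask = mask, eps0 = 1,
                      row_budget = rowSums(g0 * mask) * 100),
                 class = "gain_state")
  attr(g, "ei") <- ei
  g
}
zero_window <- function(n, L = 50) {
  list(coincidence = matrix(0, n, n), pre_mean = matrix(0, n, n),
       post_mean = rep(0, n), steps = L, qmax = 1)
}

test_that("a silent window leaves slow and structural gains untouched", {
  g <- make_gain_state()
  out <- hebbian_update(g, zero_window(4))
  expect_identical(out$g, g$g)
  expect_identical(out$rho, g$rho)
  # transient efficacy decays toward its baseline
  g2 <- g
  g2$eps <- 2 * g$mask
  out2 <- hebbian_update(g2, zero_window(4))
  expect_true(all(out2$eps[g$mask] < 2))
  expect_true(all(out2$eps[g$mask] >= 1))
})

test_that("sustained coincident firing strictly potentiates, per the stated recurrence", {
  n <- 4
  g <- make_gain_state(n)
  win <- zero_window(n)
  win$post_mean <- rep(0.8, n)
  win$pre_mean <- matrix(0.8, n, n)
  win$coincidence <- matrix(0.8 * 0.8, n, n)
  win$coincidence[2, 1] <- 0.9          # one synapse above chance
  rates <- list(normalize = FALSE)

  # oracle: apply the documented recurrence by hand for three windows
  a_g <- 1 - exp(-50 / 1000)
  a_eps <- 1 - exp(-50 / 10)
  a_th <- 1 - exp(-50 / 250)
  eps <- 1; th <- 0.64; gg <- 0.1
  traj <- numeric(3)
  cur <- g
  for (k in 1:3) {
    cv <- 0.9 - 0.8 * 0.8
    th <- th + a_th * (0.64 - th)
    gate <- max(0.8 - th, 0)
    eps <- eps + a_eps * (1 * (1 + 1 * win$coincidence[2, 1]) - eps)
    gg <- gg + 40 * a_g * eps * cv * gate
    traj[k] <- gg
    cur <- hebbian_update(cur, win, rates)
    expect_equal(cur$g[2, 1], traj[k], tolerance = 1e-12)
  }
  expect_true(all(diff(c(0.1, traj)) > 0))
})

test_that("competitive potentiation preserves the rank order of afferent drive", {
  n <- 3
  g <- make_gain_state(n, ei = rep("E", 3))
  win <- zero_window(n)
  win$post_mean <- rep(0.8, n)
  win$pre_mean <- matrix(0.5, n, n)
  win$coincidence <- matrix(0.4, n, n)
  win$coincidence[1, 2] <- 0.4 + 0.10   # afferent 2 drives twice the excess
  win$coincidence[1, 3] <- 0.4 + 0.05   # of afferent 3
  out <- hebbian_update(g, win, list(normalize = TRUE))
  expect_gt(out$g[1, 2], out$g[1, 3])
  expect_gt(out$g[1, 2] / out$g[1, 3], 1)
})

test_that("hebbian gain is non-decreasing under positive coincident flux", {
  set.seed(42)
  g <- make_gain_state(5)
  for (k in 1:20) {
    post <- runif(5, 0.5, 1)
    pre <- matrix(runif(25, 0.3, 0.9), 5, 5)
    win <- list(coincidence = pre * post + matrix(runif(25, 0, 0.1), 5, 5),
                pre_mean = pre, post_mean = post, steps = 50, qmax = 1)
    out <- hebbian_update(g, win, list(normalize = FALSE))
    expect_true(all(out$g - g$g >= -1e-15))
    g <- out
  }
})

test_that("anti-Hebbian normalization balances flux and preserves ratios", {
  n <- 4
  ei <- c("E", "E", "I", "I")
  g <- make_gain_state(n, ei = ei)
  g$g <- matrix(runif(16, 0.05, 0.2), 4, 4) * g$mask

  # already balanced window: scale factors are exactly 1
  win <- list(sum_phi_e = rep(0.5, n), sum_phi_i = rep(-0.5, n))
  out <- anti_hebbian_normalize(g, win, target = 0.5, ei = ei)
  expect_equal(out$scale_e, rep(1, n))
  expect_equal(out$scale_i, rep(1, n))
  expect_identical(out$gains$g, g$g)

  # 2:1 excitatory excess: balance to machine precision, ratios kept
  win2 <- list(sum_phi_e = rep(1.0, n), sum_phi_i = rep(-0.5, n))
  out2 <- anti_hebbian_normalize(g, win2, target = 0.5, ei = ei)
  expect_lt(out2$residual, 1e-12)
  ecol <- ei == "E"
  ratio_before <- g$g[1, 2] / g$g[3, 2]
  expect_equal(out2$gains$g[1, 2] / out2$gains$g[3, 2], ratio_before)

  # a purely excitatory field cannot balance
  expect_error(anti_hebbian_normalize(g, win2, 0.5, ei = rep("E", 4)),
               "unbalanced-field")
})

test_that("adaptive balance target preserves total coupling magnitude", {
  se <- c(1, 0.5)
  si <- c(-0.25, -2)
  tgt <- balance_target(se, si)
  expect_equal(tgt, sqrt(se * abs(si)))
  # geometric-mean scaling leaves the product of block fluxes unchanged
  expect_equal((tgt / se) * (tgt / abs(si)), rep(1, 2))
})

test_that("in-run balance residuals are at machine precision", {
  f <- small_field()
  d <- white_noise_drive(16, 600, 0.2, seed = 3)
  rec <- simulate_field(f, 600, drive = d)
  expect_gt(nrow(rec$balance), 0)
  expect_true(all(rec$balance$residual < 1e-6))
})
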