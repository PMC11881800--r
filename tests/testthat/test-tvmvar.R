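test_that("ADF test separates random walks from stationary noise", {
  # Monte-Carlo under the unit-root null and the stationary alternative
  set.seed(1)
  n_runs <- 120
  null_reject <- logical(n_runs); alt_reject <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    rw <- cumsum(rnorm(200))
    wn <- rnorm(200)
    null_reject[i] <- adf_stationarity_test(rw)$reject_unit_root
    alt_reject[i] <- adf_stationarity_test(wn)$reject_unit_root
  }
  expect_lt(mean(null_reject), 0.10)   # fail to reject in >= 90% of runs
  expect_gt(mean(alt_reject), 0.90)
  expect_error(adf_stationarity_test(rep(1, 50)), class = "tpdc_degenerate_error")
  expect_error(adf_stationarity_test(rnorm(10)), class = "tpdc_parameter_error")
})

test_that("SBC order selection recovers a planted VAR(3)", {
  A1 <- matrix(c(0.4, 0.3, 0, 0.4), 2)
  A3 <- matrix(c(-0.4, 0, 0.3, -0.4), 2)
  hits <- 0
  for (s in 1:15) {
    set.seed(s)
    n <- 2500
    x <- matrix(rnorm(2 * n), n, 2)
    for (t in 4:n)
      x[t, ] <- A1 %*% x[t - 1, ] + A3 %*% x[t - 3, ] + rnorm(2)
    if (select_model_order(x, 1, 6) == 3) hits <- hits + 1
  }
  expect_gte(hits / 15, 0.8)
  # white noise selects p_min; forced range returns the forced order
  set.seed(2)
  wn <- matrix(rnorm(3000), 1000, 3)
  expect_equal(c(select_model_order(wn, 1, 5)), 1)
  expect_equal(c(select_model_order(wn, 5, 5)), 5)
  expect_error(select_model_order(wn, 4, 2), class = "tpdc_parameter_error")
})

test_that("dual-EKF time averages agree with the least-squares oracle", {
  A <- matrix(c(0.5, 0.4, 0, 0.3), 2)
  x <- sim_var1(A, 10000, seed = 3)
  fit <- tvmvar(x, P = 1)
  ols <- lm(x[-1, 2] ~ 0 + x[-10000, 1] + x[-10000, 2])
  expect_equal(coef(fit)[1, 2, 1], unname(coef(ols)[1]), tolerance = 0.05)
  expect_equal(coef(fit)[1, 2, 2], unname(coef(ols)[2]), tolerance = 0.05)
  # zero coupling: off-diagonal averages within +-0.05 of 0
  x0 <- sim_var1(diag(0.3, 2), 8000, seed = 4)
  fit0 <- tvmvar(x0, P = 1)
  cf <- coef(fit0)[1, , ]
  expect_lt(max(abs(cf[row(cf) != col(cf)])), 0.05)
})

test_that("dual-EKF tracks a coefficient step", {
  set.seed(9)
  n <- 6000
  x <- matrix(rnorm(2 * n), n, 2)
  for (t in 2:n) {
    a <- if (t > n / 2) 0.6 else 0
    x[t, 2] <- x[t, 2] + a * x[t - 1, 1] + 0.3 * x[t - 1, 2]
  }
  fit <- tvmvar(x, P = 1)
  path <- fit$coeffs[, 1, 2, 1]
  expect_gte(mean(path[(n / 2 + 500):n]) - mean(path[500:(n / 2)]), 0.4)
})

test_that("tvmvar methods are coherent", {
  x <- sim_var1(matrix(c(0.5, 0.4, 0, 0.3), 2), 2000, seed = 5)
  colnames(x) <- c("a", "b")
  fit <- tvmvar(x, P = 1)
  expect_s3_class(fit, "tvmvar")
  expect_equal(dim(coef(fit, "path")), c(2000, 1, 2, 2))
  expect_equal(dim(residuals(fit)), dim(x))
  # one-step prediction matches the hand-rolled recursion
  pr <- predict(fit, n_ahead = 1)
  A_end <- fit$coeffs[2000, 1, , ]
  manual <- as.numeric(A_end %*% fit$series[2000, ])
  expect_equal(unname(pr[1, ]), manual, tolerance = 1e-10)
  # simulate() returns a series reproducing the coupling scale
  y <- simulate(fit, nsim = 5000, seed = 6)
  b_hat <- unname(coef(lm(y[-1, 2] ~ 0 + y[-5000, 1] + y[-5000, 2]))[1])
  expect_equal(b_hat, coef(fit)[1, 2, 1], tolerance = 0.1)
  expect_output(print(fit), "Time-varying MVAR")
  expect_output(print(summary(fit)), "coefficient time-averages")
})
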