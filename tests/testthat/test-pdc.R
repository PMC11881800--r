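test_that("identity models give diagonal PDC at every frequency", {
  x <- matrix(rnorm(2000 * 3), 2000, 3)
  fit <- tvmvar(x, P = 1, fs = 1)
  fit$coeffs[] <- 0
  g <- spectral_grid(1, n_freq = 16, band = c(0.05, 0.2))
  p <- pdc_spectrum(fit, g, t = 1000)
  for (f in seq_len(16)) {
    expect_equal(diag(p[, , f]), rep(1, 3), tolerance = 1e-12)
    off <- p[, , f][row(p[, , f]) != col(p[, , f])]
    expect_lt(max(abs(off)), 1e-12)
  }
})

test_that("PDC satisfies column normalization on random stable models", {
  for (s in 1:6) {
    net <- generate_network(5, edge_density = 0.4, seed = s)
    sim <- simulate_roi_timeseries(net, 800, seed = s)
    fit <- tvmvar(sim$series, P = 2, fs = sim$fs)
    g <- spectral_grid(sim$fs)
    for (t in c(100, 400, 800)) {
      p <- pdc_spectrum(fit, g, t)
      norms <- apply(p^2, c(2, 3), sum)   # per source column and frequency
      expect_lt(max(abs(norms - 1)), 1e-6)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("bivariate PDC matches a brute-force complex oracle to 1e-10", {
  a <- matrix(c(0.5, 0.4, 0, 0.3), 2)   # a[i, j]: j -> i
  A <- array(0, dim = c(1, 2, 2)); A[1, , ] <- a
  for (lam in c(0.05, 0.1, 0.25)) {
    p <- tpdc:::pdc_from_coeffs(A, lam, 1)[, , 1]
    expect_equal(p, pdc_oracle_var1(a, lam, 1), tolerance = 1e-10)
  }
})

test_that("tpdc reports exactly 42 off-diagonal connections for 7 ROIs", {
  net <- generate_network(7, edge_density = 0.2, seed = 2)
  sim <- simulate_roi_timeseries(net, 700, seed = 2)
  res <- tpdc(sim$series, fs = sim$fs, order = 1, check_stationarity = FALSE)
  ct <- connection_table(res)
  expect_equal(nrow(ct), 42)
  expect_true(all(is.na(diag(res$band_time_average))))
  expect_true(all(ct$value >= 0 & ct$value <= 1))
})

test_that("planted directed edges dominate their reverse direction", {
  wins <- 0
  for (s in 1:8) {
    net <- generate_network(4, edge_density = 0, seed = s)
    net$edges <- data.frame(source = 1L, target = 2L, coupling = 0.5,
                            lag = 1L, tv_profile = "constant")
    sim <- simulate_roi_timeseries(net, 1500, seed = s + 40)
    res <- tpdc(sim$series, fs = sim$fs, order = 1, check_stationarity = FALSE)
    m <- res$band_time_average
    if (m[2, 1] > m[1, 2]) wins <- wins + 1
  }
  expect_gte(wins / 8, 0.9)
})

test_that("hemisphere averaging is an element-wise mean", {
  net <- generate_network(7, edge_density = 0.2, seed = 3)
  simL <- simulate_roi_timeseries(net, 600, seed = 3)
  simR <- simulate_roi_timeseries(net, 600, seed = 4)
  L <- tpdc(simL$series, fs = simL$fs, order = 1, check_stationarity = FALSE)
  R <- tpdc(simR$series, fs = simR$fs, order = 1, check_stationarity = FALSE)
  avg <- average_hemispheres(L, R)
  expect_equal(avg$band_time_average,
               (L$band_time_average + R$band_time_average) / 2)
  # idempotence and linearity
  expect_equal(average_hemispheres(L, L)$band_time_average, L$band_time_average)
  Z <- L; Z$band_time_average[] <- 0
  expect_equal(average_hemispheres(Z, R)$band_time_average,
               R$band_time_average / 2)
  # mismatched ROI sets -> schema error
  R2 <- R; R2$labels <- rev(R2$labels)
  expect_error(average_hemispheres(L, R2), class = "tpdc_schema_error")
})

test_that("grid validation rejects bands outside the Nyquist range", {
  expect_error(spectral_grid(0.3, band = c(0.2, 0.5)), class = "tpdc_grid_error")
  expect_error(spectral_grid(-1), class = "tpdc_grid_error")
  g <- spectral_grid(7.8125)
  expect_true(all(g$frequencies > 0 & g$frequencies <= 7.8125 / 2))
  expect_true(any(g$band_mask))
})
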