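test_that("edge generation respects density bounds", {
  expect_equal(nrow(generate_network(7, edge_density = 0, seed = 1)$edges), 0)
  net_full <- generate_network(7, edge_density = 1, coupling_range = c(0.05, 0.1),
                               seed = 1)
  expect_equal(nrow(net_full$edges), 42)
  expect_false(any(net_full$edges$source == net_full$edges$target))
  expect_false(any(duplicated(net_full$edges[, c("source", "target")])))
})

test_that("generated networks are stable by the companion eigenvalue oracle", {
  for (s in 1:5) {
    net <- generate_network(7, edge_density = 0.3, seed = s)
    # independent oracle: build the companion matrix by hand
    n <- net$n_rois
    A1 <- diag(net$self_coef, n)
    for (i in seq_len(nrow(net$edges)))
      A1[net$edges$target[i], net$edges$source[i]] <-
        A1[net$edges$target[i], net$edges$source[i]] + net$edges$coupling[i]
    expect_lt(max(Mod(eigen(A1, only.values = TRUE)$values)), 1)
  }
  # 3-cycle at coupling 0.9, order 1: oracle says the stabilised network
  # must have companion spectral radius < 1
  net3 <- generate_network(3, edge_density = 1, coupling_range = c(0.85, 0.9),
                           self_coef = 0.5, seed = 2)
  C <- companion_matrix(tpdc:::network_coef_array(net3))
  expect_lt(max(Mod(eigen(C, only.values = TRUE)$values)), 1)
})

test_that("MVAR simulation reproduces planted couplings (OLS oracle)", {
  # no coupling: channels mutually independent white-ish noise
  net0 <- generate_network(3, edge_density = 0, self_coef = 0, seed = 1)
  sim0 <- simulate_roi_timeseries(net0, 4000, seed = 3)
  cc <- cor(sim0$series[-1, ], sim0$series[-4000, ])
  expect_lt(max(abs(cc[row(cc) != col(cc)])), 0.06)
  expect_lt(max(abs(colMeans(sim0$series))), 0.1)

  # planted 1 -> 2 edge at 0.5, lag-1 regression oracle at n = 10000
  net <- generate_network(2, edge_density = 0, self_coef = 0.3, seed = 1)
  net$edges <- data.frame(source = 1L, target = 2L, coupling = 0.5,
                          lag = 1L, tv_profile = "constant")
  sim <- simulate_roi_timeseries(net, 10000, seed = 4)
  y <- sim$series
  fit <- lm(y[-1, 2] ~ y[-10000, 1] + y[-10000, 2])
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.05)
})

test_that("step time-varying profile switches the edge on mid-series", {
  net <- generate_network(2, edge_density = 0, self_coef = 0.3, seed = 1)
  net$edges <- data.frame(source = 1L, target = 2L, coupling = 0.5,
                          lag = 1L, tv_profile = "step")
  sim <- simulate_roi_timeseries(net, 8000, seed = 5)
  y <- sim$series
  ols_half <- function(idx) {
    unname(coef(lm(y[idx + 1, 2] ~ y[idx, 1] + y[idx, 2]))[2])
  }
  expect_lt(abs(ols_half(1:3900)), 0.08)
  expect_equal(ols_half(4100:7999), 0.5, tolerance = 0.08)
})

test_that("generators are reproducible and validate inputs", {
  a <- simulate_roi_timeseries(generate_network(seed = 7), 300, seed = 9)
  b <- simulate_roi_timeseries(generate_network(seed = 7), 300, seed = 9)
  expect_identical(a$series, b$series)
  expect_error(generate_network(edge_density = 2), "edge_density")
  expect_error(simulate_roi_timeseries(generate_network(seed = 1), 5),
               class = "tpdc_parameter_error")
  # unstable after retries
  expect_error(generate_network(3, edge_density = 1, coupling_range = c(0.9, 0.95),
                                self_coef = 0.99, seed = 1, max_retries = 0),
               class = "tpdc_stability_error")
})
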