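test_that("bootstrap configuration is validated", {
  expect_error(bootstrap_config(n_windows = 1), class = "tpdc_parameter_error")
  expect_error(bootstrap_config(percentile = 100), class = "tpdc_parameter_error")
  y <- matrix(rnorm(300 * 3), 300, 3)
  expect_error(bootstrap_threshold(y, bootstrap_config(10, n_windows = 100),
                                   fs = 1, grid = spectral_grid(1, band = c(0.05, 0.2)),
                                   order = 2),
               class = "tpdc_parameter_error")
})

test_that("trailing samples are truncated to the largest K multiple", {
  y <- matrix(rnorm(1005 * 3), 1005, 3)
  expect_message(
    bootstrap_threshold(y, bootstrap_config(5, n_windows = 10, seed = 1),
                        fs = 1, grid = spectral_grid(1, band = c(0.05, 0.2)),
                        order = 1),
    "truncating 5")
})

test_that("a planted strong edge is detected against the shuffle null", {
  hits <- 0
  for (s in 1:5) {
    net <- generate_network(3, edge_density = 0, seed = s)
    net$edges <- data.frame(source = 1L, target = 2L, coupling = 0.7,
                            lag = 1L, tv_profile = "constant")
    net <- structure(net, class = "tpdc_network")
    sim <- simulate_roi_timeseries(net, 3000, seed = s + 10)
    bt <- bootstrap_threshold(sim$series,
                              bootstrap_config(60, n_windows = 10, seed = s),
                              fs = sim$fs, order = 1)
    if (isTRUE(bt$significant_mask[2, 1])) hits <- hits + 1
  }
  expect_gte(hits / 5, 0.9)
})

test_that("null thresholds are stable across seeds", {
  set.seed(7)
  y <- matrix(rnorm(2000 * 3), 2000, 3)
  g <- spectral_grid(1, band = c(0.05, 0.2))
  t1 <- bootstrap_threshold(y, bootstrap_config(300, 10, seed = 1), fs = 1,
                            grid = g, order = 1)$thresholds
  t2 <- bootstrap_threshold(y, bootstrap_config(300, 10, seed = 2), fs = 1,
                            grid = g, order = 1)$thresholds
  rel <- abs(t1 - t2) / t1
  expect_lt(max(rel, na.rm = TRUE), 0.10)
})

test_that("final mask is always a subset of the bootstrap mask", {
  net <- generate_network(3, edge_density = 0.5, seed = 3)
  sim <- simulate_roi_timeseries(net, 1500, seed = 3)
  sig <- significance_test(sim$series, bootstrap_config(40, 10, seed = 3),
                           fs = sim$fs, order = 1)
  expect_true(all(sig$final_mask[!is.na(sig$final_mask)] <=
                    sig$significant_mask[!is.na(sig$significant_mask)]))
  expect_equal(nrow(sig$table), 6)  # 3 ROIs -> 6 ordered pairs
})

test_that("white-noise forward-reversed asymmetry is centred at zero", {
  set.seed(5)
  y <- matrix(rnorm(2000 * 3), 2000, 3)
  tr <- time_reversal_test(y, bootstrap_config(60, 10, seed = 5), fs = 1,
                           grid = spectral_grid(1, band = c(0.05, 0.2)), order = 1)
  expect_lt(max(abs(tr$statistic), na.rm = TRUE), 0.1)
  expect_equal(sum(tr$trt_mask, na.rm = TRUE), 0)
})

test_that("subject summaries count prevalences correctly", {
  net <- generate_network(7, edge_density = 0.15, seed = 4)
  sim <- simulate_roi_timeseries(net, 1200, seed = 4)
  sig <- significance_test(sim$series, bootstrap_config(30, 10, seed = 4),
                           fs = sim$fs, order = 1, trt = FALSE)
  sm <- summarize_connections(list(sig, sig))
  expect_equal(nrow(sm$table), 42)
  expect_equal(sm$n_subjects, 2)
  # counting oracle: prevalence is the mean of the per-subject finals
  expect_equal(sm$table$prevalence, as.numeric(sig$table$final))
  # single subject, all passing
  sig2 <- sig
  sig2$table$final <- TRUE
  expect_true(all(summarize_connections(list(sig2))$table$prevalence == 1))
  expect_error(summarize_connections(list()), class = "tpdc_empty_error")
})
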