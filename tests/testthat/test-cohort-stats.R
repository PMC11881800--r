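test_that("PCA eigen-structure matches closed-form oracles", {
  set.seed(1)
  n <- 4000
  # mutually independent variables: all eigenvalues near 1
  X <- as.data.frame(matrix(rnorm(n * 10), n))
  names(X) <- clinical_variables()
  X$group <- "CI"
  p_ind <- run_pca(X, rotation = "none")
  expect_lt(max(abs(p_ind$eigenvalues - 1)), 0.15)
  # two perfectly correlated variables among independents: leading
  # eigenvalue of the 2-block is 2
  X2 <- X
  X2$age_first_ha <- X2$age_first_ci
  p_dup <- run_pca(X2, rotation = "none")
  expect_equal(p_dup$eigenvalues[1], 2, tolerance = 0.1)
})

test_that("the synthetic cohort yields three components with block loadings", {
  coh <- generate_cohort(cohort_spec(seed = 2))
  p <- run_pca(coh$clinical)
  expect_equal(p$n_retained, 3)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  # block variables load together: for each block there is one component
  # on which all its members have |loading| > 0.5
  blocks <- list(primary = c("age_first_ci", "age_first_ha",
                             "dur_deaf_first_ci", "dur_deaf_left_ci"),
                 secondary = c("dur_deaf_right_ci", "time_between_bilateral",
                               "age_bilateral_ci"),
                 development = c("age_at_testing", "head_size", "hearing_age"))
  used <- integer(0)
  for (b in blocks) {
    hit <- which(apply(abs(p$loadings[b, , drop = FALSE]) > 0.5, 2, all))
    expect_gte(length(hit), 1)
    used <- c(used, hit[1])
  }
  expect_equal(length(unique(used)), 3)
  # unrotated scores are uncorrelated
  g <- crossprod(scale(p$scores_unrotated, scale = FALSE))
  expect_lt(max(abs(g[row(g) != col(g)])) / nrow(p$scores_unrotated), 1e-8)
})

test_that("mediation paths obey the linear identity and recover planted effects", {
  set.seed(3)
  n <- 500
  x <- rnorm(n)
  m <- -0.5 * x + rnorm(n, sd = sqrt(0.75))
  y <- 0.4 * m + 0.2 * x + rnorm(n)
  fit <- fit_mediation(x, m, y, n_boot = 300, seed = 3)
  expect_equal(fit$total, fit$cprime + fit$indirect, tolerance = 1e-6)
  expect_equal(fit$a, unname(coef(lm(m ~ x))[2]), tolerance = 1e-10)
  expect_equal(fit$b, unname(coef(lm(y ~ m + x))[2]), tolerance = 1e-10)
  # b = 0 in the generating model: CI covers 0 in most runs
  cover <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(200); m <- 0.5 * x + rnorm(200); y0 <- rnorm(200)
    ci <- fit_mediation(x, m, y0, n_boot = 300, seed = s)$ci
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.85)
  expect_error(fit_mediation(x[1:5], m[1:5], y[1:5]),
               class = "tpdc_parameter_error")
  expect_error(fit_mediation(x, rep(1, n), y), class = "tpdc_degenerate_error")
})

test_that("BH adjustment matches the hand step-up computation", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(bh_adjust(p), rep(0.05, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  # hand oracle on an unsorted vector: p(i) * m / i with cumulative minimum
  set.seed(4)
  praw <- runif(9)
  ord <- order(praw)
  m <- length(praw)
  hand <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, praw[ord[i]] * m / i)
    hand[ord[i]] <- min(running, 1)
  }
  expect_equal(bh_adjust(praw), hand)
  expect_true(all(bh_adjust(praw) >= praw))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "tpdc_domain_error")
})

test_that("the mediation battery enumerates 252 tests per component", {
  coh <- generate_cohort(cohort_spec(seed = 5))
  ci <- coh$clinical$group == "CI"
  p <- run_pca(coh$clinical)
  bat <- run_mediation_battery(p, coh$connections[ci, ],
                               coh$reading[ci, ], n_boot = 60, seed = 5)
  expect_equal(nrow(bat), 252 * p$n_retained)
  expect_equal(sum(bat$predictor == "PC1"), 252)
  expect_true(all(bat$p_bh >= bat$p_raw - 1e-12))
  # misaligned subjects -> join error
  bad <- coh$reading[ci, ]
  bad$subject <- paste0("X", bad$subject)
  expect_error(run_mediation_battery(p, coh$connections[ci, ], bad),
               class = "tpdc_join_error")
})

test_that("planted mediations are recovered with controlled false discoveries", {
  # detection through a BH family of 252 tests needs strong
  # mediator-outcome paths and a moderately sized cohort; plant 10 effects
  eff <- data.frame(predictor = "PC1",
                    connection = connection_pairs_df(roi_labels())$source[1:10],
                    subtest = rep(subtest_labels()[1:5], 2),
                    a = -0.15, b = 33)
  pairs <- connection_pairs_df(roi_labels())
  eff$connection <- paste0(pairs$source[1:10], "->", pairs$target[1:10])
  rec <- 0; fd <- 0; calls <- 0
  for (s in 1:3) {
    coh <- generate_cohort(cohort_spec(n_ci = 100, mediation_effects = eff, seed = s))
    ci <- coh$clinical$group == "CI"
    p <- run_pca(coh$clinical)
    bat <- run_mediation_battery(p, coh$connections[ci, ], coh$reading[ci, ],
                                 n_boot = 3000, seed = s)
    planted <- paste(eff$connection, eff$subtest)
    # the planted factor may land on any rotated component; use the one
    # with the most discoveries
    per_pc <- split(bat, bat$predictor)
    best <- per_pc[[which.max(vapply(per_pc, function(b) sum(b$significant), 0))]]
    hit <- best$significant & paste(best$connection, best$subtest) %in% planted
    rec <- rec + sum(hit)
    fd <- fd + sum(best$significant) - sum(hit)
    calls <- calls + sum(best$significant)
  }
  expect_gte(rec / 3, 6)                   # >= 6 of 10 recovered on average
  if (calls > 0) expect_lte(fd / calls, 0.15)
})

test_that("group comparisons match exact small-sample oracles", {
  r <- data.frame(group = rep(c("A", "B"), each = 3),
                  WRDC = c(1, 2, 3, 4, 5, 6))
  out <- compare_groups(r)
  expect_equal(out$U, 0)            # all B exceed all A
  # identical groups: t = 0, p = 1
  r2 <- data.frame(group = rep(c("A", "B"), each = 4), WRDC = rep(1:4, 2))
  out2 <- compare_groups(r2)
  expect_equal(out2$t, 0)
  expect_equal(out2$p_welch, 1)
  expect_error(compare_groups(data.frame(group = c("A", "A", "B"),
                                         WRDC = c(1, 2, 3))),
               class = "tpdc_sample_size_error")
  # power under a 1 SD shift at n = 50/25
  rej <- vapply(1:60, function(s) {
    set.seed(s)
    d <- data.frame(group = rep(c("CI", "TH"), c(50, 25)),
                    WRDC = c(rnorm(50, 250, 15), rnorm(25, 265, 15)))
    compare_groups(d)$p_welch < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("reading regressions report exact and null R-squared correctly", {
  x <- data.frame(hearing_age = 1:20)
  r <- data.frame(WRDC = 3 + 2 * (1:20))
  fit <- suppressWarnings(fit_reading_regression(r, x))  # exact fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope_hearing_age, 2, tolerance = 1e-10)
  set.seed(6)
  xn <- data.frame(a = rnorm(1000), b = rnorm(1000))
  rn <- data.frame(WRDC = rnorm(1000))
  fitn <- fit_reading_regression(rn, xn)
  expect_lt(fitn$r_squared, 0.02)   # ~ k/(n-1)
  xc <- data.frame(a = 1:20, b = 2 * (1:20))
  expect_error(fit_reading_regression(data.frame(WRDC = rnorm(20)), xc),
               class = "tpdc_collinearity_error")
})
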