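# Shared oracles and fixture builders, independent of the package internals
# they are used to check.

# rank-based AUC for planted-edge recovery
rank_auc <- function(score, label) {
  r <- rank(score)
  pos <- sum(label)
  (sum(r[label]) - pos * (pos + 1) / 2) / (pos * sum(!label))
}

# simulate a bivariate VAR(1) with coefficient matrix A (target x source)
sim_var1 <- function(A, n, seed, sd = 1) {
  set.seed(seed)
  k <- nrow(A)
  x <- matrix(0, n, k)
  e <- matrix(rnorm(n * k, sd = sd), n, k)
  for (t in 2:n) x[t, ] <- A %*% x[t - 1, ] + e[t, ]
  x
}

# planted-edge labels for a network over the 42 ordered pairs
edge_labels <- function(net, labels = roi_labels()) {
  ct <- connection_pairs_df(labels)
  truth <- paste(net$edges$source, net$edges$target)
  paste(match(ct$source, labels), match(ct$target, labels)) %in% truth
}

connection_pairs_df <- function(labels) {
  g <- expand.grid(target = labels, source = labels, stringsAsFactors = FALSE)
  g <- g[g$target != g$source, c("source", "target")]
  rownames(g) <- NULL
  g
}

# brute-force PDC at one frequency from lag-1 coefficient matrix a
# (a[i, j] = influence of j on i), fs in Hz
pdc_oracle_var1 <- function(a, lambda, fs) {
  z <- exp(-1i * 2 * pi * lambda / fs)
  Abar <- diag(nrow(a)) - a * z
  mag <- abs(Abar)
  sweep(mag, 2, sqrt(colSums(mag^2)), "/")
}

# clean tiny recording for preprocessing tests
make_clean_recording <- function(n_samples = 400, seed = 1, noise = 0,
                                 artifacts = artifact_spec(0, 0, 0, 0, 0, 0)) {
  net <- generate_network(edge_density = 0.15, seed = seed)
  sim <- simulate_roi_timeseries(net, n_samples, seed = seed)
  list(sim = sim,
       rec = synthesize_raw_recording(sim, artifacts = artifacts,
                                      channel_noise_sd = noise, seed = seed + 50))
}

detrend_oracle <- function(v) unname(stats::residuals(stats::lm(v ~ seq_along(v))))
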