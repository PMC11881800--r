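#' Generate a ground-truth directed ROI network
#'
#' Draws a random directed network over `n_rois` regions whose edges carry
#' lag-1 multivariate autoregressive (MVAR) couplings. Each region also has a
#' slow autoregressive pole (`self_coef`, default 0.95) so that the latent
#' dynamics concentrate their power in the low-frequency haemodynamic band.
#' The implied MVAR is checked for stability (spectral radius of its companion
#' matrix `< 1`); if unstable, cross-couplings are shrunk and the check is
#' repeated up to `max_retries` times.
#'
#' @param n_rois Number of regions (default 7, the reading network).
#' @param edge_density Probability in `[0, 1]` that each ordered pair of
#'   distinct regions carries an edge; `1` yields all `n(n-1)` edges.
#' @param coupling_range Length-2 numeric, magnitude range of edge couplings;
#'   must lie within `(-1, 1)`.
#' @param model_order MVAR lag order `P` of the generated model.
#' @param tv_profile Time-modulation profile applied to every edge:
#'   `"constant"`, `"ramp"` (linear 0 to 1 over the recording) or `"step"`
#'   (off in the first half, on in the second).
#' @param self_coef Lag-1 self-dynamics pole controlling the spectral
#'   concentration of each region's own dynamics (default 0.98, placing
#'   most latent power in the low-frequency haemodynamic band).
#' @param seed Integer seed; all generators take explicit seeds.
#' @param max_retries Stability retries before failing.
#' @return Object of class `tpdc_network`: list with `n_rois`, `edges`
#'   (data frame `source`, `target`, `coupling`, `lag`, `tv_profile`),
#'   `model_order`, `self_coef`.
#' @examples
#' net <- generate_network(n_rois = 7, edge_density = 0.15, seed = 1)
#' nrow(net$edges)
#' @export
generate_network <- function(n_rois = 7, edge_density = 0.15,
                             coupling_range = c(0.3, 0.6), model_order = 1,
                             tv_profile = "constant", self_coef = 0.98,
                             seed = 0, max_retries = 25) {
  stopifnot(n_rois >= 1, model_order >= 1)
  if (edge_density < 0 || edge_density > 1)
    stop_tpdc("tpdc_parameter_error", "edge_density must be in [0, 1]")
  if (any(abs(coupling_range) >= 1))
    stop_tpdc("tpdc_parameter_error", "coupling_range must lie within (-1, 1)")
  tv_profile <- match.arg(tv_profile, c("constant", "ramp", "step"))

  with_seed(seed, {
    pairs <- connection_pairs(seq_len(n_rois))
    keep <- stats::runif(nrow(pairs)) < edge_density
    edges <- pairs[keep, , drop = FALSE]
    edges$coupling <- stats::runif(nrow(edges), min(coupling_range), max(coupling_range))
    edges$lag <- rep(1L, nrow(edges))
    edges$tv_profile <- rep(tv_profile, length.out = nrow(edges))
    rownames(edges) <- NULL

    net <- structure(list(n_rois = as.integer(n_rois), edges = edges,
                          model_order = as.integer(model_order),
                          self_coef = self_coef),
                     class = "tpdc_network")
    for (i in seq_len(max_retries + 1L)) {
      if (network_is_stable(net)) return(net)
      net$edges$coupling <- net$edges$coupling * 0.7
    }
    stop_tpdc("tpdc_stability_error",
              "could not stabilise network after %d retries", max_retries)
  })
}

# internal: P x n x n coefficient array at full edge strength (tv modulation
# is applied at simulation time)
network_coef_array <- function(network, modulation = 1) {
  n <- network$n_rois; P <- network$model_order
  A <- array(0, dim = c(P, n, n))
  for (k in seq_len(n)) A[1, k, k] <- network$self_coef
  e <- network$edges
  if (nrow(e)) {
    mod <- rep(modulation, length.out = nrow(e))
    for (i in seq_len(nrow(e)))
      A[e$lag[i], e$target[i], e$source[i]] <-
        A[e$lag[i], e$target[i], e$source[i]] + e$coupling[i] * mod[i]
  }
  A
}

#' Companion matrix of an MVAR coefficient array
#'
#' @param A Array `P x n x n` of lag coefficient matrices.
#' @return The `nP x nP` companion matrix.
#' @export
companion_matrix <- function(A) {
  P <- dim(A)[1]; n <- dim(A)[2]
  C <- matrix(0, n * P, n * P)
  for (r in seq_len(P)) C[seq_len(n), (r - 1) * n + seq_len(n)] <- A[r, , ]
  if (P > 1) C[n + seq_len(n * (P - 1)), seq_len(n * (P - 1))] <- diag(n * (P - 1))
  C
}

# internal: stability at full edge strength (the worst case across tv profiles,
# which only scale edges in [0, 1])
network_is_stable <- function(network) {
  C <- companion_matrix(network_coef_array(network))
  max(Mod(eigen(C, only.values = TRUE)$values)) < 1
}

# internal: per-edge modulation factor at relative time u in [0, 1]
tv_modulation <- function(profile, u) {
  switch(profile,
         constant = rep(1, length(u)),
         ramp = u,
         step = as.numeric(u >= 0.5),
         stop_tpdc("tpdc_parameter_error", "unknown tv_profile '%s'", profile))
}

#' Simulate latent ROI time series from a ground-truth network
#'
#' Runs the (possibly time-varying) MVAR recursion
#' \eqn{x(t) = \sum_{r=1}^{P} a_r(t) x(t-r) + \eta(t)}
#' with zero-mean Gaussian innovations. A stationary burn-in stretch is
#' discarded so the returned series starts in the process's stationary
#' regime.
#'
#' @param network A `tpdc_network`.
#' @param n_samples Number of returned samples; must exceed
#'   `10 * model_order`.
#' @param fs Sampling rate in Hz (default 7.8125, typical continuous-wave
#'   fNIRS).
#' @param noise_sd Innovation standard deviation.
#' @param seed Integer seed.
#' @param burn_in Discarded leading samples.
#' @return List with `series` (matrix `n_samples x n_rois`, time in rows),
#'   `fs`, `network` and `truth` (the edge data frame).
#' @export
simulate_roi_timeseries <- function(network, n_samples, fs = 7.8125,
                                    noise_sd = 1, seed = 0, burn_in = 200) {
  if (!inherits(network, "tpdc_network"))
    stop_tpdc("tpdc_parameter_error", "network must be a tpdc_network")
  if (n_samples <= 10 * network$model_order)
    stop_tpdc("tpdc_parameter_error", "n_samples must exceed 10 * model_order")
  if (fs <= 0) stop_tpdc("tpdc_parameter_error", "fs must be positive")
  if (!network_is_stable(network))
    stop_tpdc("tpdc_stability_error", "network is unstable")

  n <- network$n_rois; P <- network$model_order
  total <- n_samples + burn_in
  e <- network$edges
  with_seed(seed, {
    eta <- matrix(stats::rnorm(total * n, sd = noise_sd), total, n)
    x <- matrix(0, total, n)
    base <- network_coef_array(network, modulation = 0)  # self dynamics only
    for (t in seq_len(total)) {
      # relative time measured over the returned (post burn-in) stretch
      u <- min(max((t - burn_in) / n_samples, 0), 1)
      xt <- eta[t, ]
      for (r in seq_len(min(P, t - 1))) xt <- xt + base[r, , ] %*% x[t - r, ]
      if (nrow(e)) for (i in seq_len(nrow(e))) {
        r <- e$lag[i]
        if (t - r >= 1)
          xt[e$target[i]] <- xt[e$target[i]] +
            e$coupling[i] * tv_modulation(e$tv_profile[i], u) * x[t - r, e$source[i]]
      }
      x[t, ] <- xt
    }
    series <- x[burn_in + seq_len(n_samples), , drop = FALSE]
    colnames(series) <- if (n == 7) roi_labels() else paste0("roi", seq_len(n))
    list(series = series, fs = fs, network = network, truth = e)
  })
}
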