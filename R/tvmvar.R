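# internal: coerce ROI time-series objects / matrices to time x channel
as_series_matrix <- function(series) {
  if (inherits(series, "tpdc_roits")) {
    out <- t(series$series)
    attr(out, "fs") <- series$fs
    return(out)
  }
  m <- as.matrix(series)
  if (is.null(colnames(m))) colnames(m) <- paste0("ch", seq_len(ncol(m)))
  m
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Regression of the first difference on the lagged level, lagged
#' differences and a constant; the t-statistic of the lagged-level
#' coefficient is compared with MacKinnon response-surface critical values
#' for the constant-only case. Rejecting the unit-root null supports
#' (second-order) stationarity.
#'
#' @param x Numeric vector, at least 20 samples.
#' @param max_lag Number of lagged differences; default
#'   `trunc((length(x) - 1)^(1/3))`.
#' @param level Significance level, one of 0.01, 0.05, 0.10 (default 0.05).
#' @return List with `statistic`, `critical`, `lags`, `reject_unit_root`.
#' @export
adf_stationarity_test <- function(x, max_lag = NULL, level = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20) stop_tpdc("tpdc_parameter_error", "need at least 20 samples")
  if (stats::sd(x) == 0)
    stop_tpdc("tpdc_degenerate_error", "constant series has no unit-root test")
  k <- max_lag %||% trunc((n - 1)^(1 / 3))
  k <- max(0L, as.integer(k))
  dx <- diff(x)
  m <- length(dx) - k
  y <- dx[(k + 1):length(dx)]
  X <- cbind(intercept = 1, level = x[(k + 1):(n - 1)])
  if (k > 0)
    for (i in seq_len(k)) X <- cbind(X, dx[(k + 1 - i):(length(dx) - i)])
  fit <- stats::lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / (m - ncol(X))
  XtXi <- chol2inv(chol(crossprod(X)))
  tstat <- fit$coefficients["level"] / sqrt(s2 * XtXi[2, 2])
  Tn <- m
  crit_tab <- list(`0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
                   `0.05` = c(-2.86154, -2.8903, -4.234, -40.04),
                   `0.1`  = c(-2.56677, -1.5384, -2.809, 0))
  key <- as.character(level)
  if (!key %in% names(crit_tab))
    stop_tpdc("tpdc_parameter_error", "level must be 0.01, 0.05 or 0.10")
  cc <- crit_tab[[key]]
  crit <- cc[1] + cc[2] / Tn + cc[3] / Tn^2 + cc[4] / Tn^3
  list(statistic = unname(tstat), critical = crit, lags = k,
       reject_unit_root = unname(tstat < crit))
}

#' Fit a stationary MVAR model by least squares
#'
#' Ordinary least-squares fit of an order-`P` multivariate autoregression,
#' conditioning on the first `P` samples (ARFIT-style). Used for order
#' selection, the bootstrap null statistic, and as the stationary reference
#' for the dual-EKF estimator.
#'
#' @param series Time x channel matrix (zero-mean) or `tpdc_roits`.
#' @param P Lag order.
#' @return List with `A` (array `P x n x n`, `A[r, i, j]` is the influence of
#'   channel j at lag r on channel i), `sigma` (innovation covariance),
#'   `residuals`, `logdet_sigma`, `n_eff`.
#' @export
fit_mvar_ols <- function(series, P) {
  y <- as_series_matrix(series)
  n <- ncol(y); T_ <- nrow(y)
  if (T_ <= n * P + 1)
    stop_tpdc("tpdc_parameter_error", "series too short for order %d", P)
  idx <- (P + 1):T_
  X <- do.call(cbind, lapply(seq_len(P), function(r) y[idx - r, , drop = FALSE]))
  Y <- y[idx, , drop = FALSE]
  qx <- qr(X)
  B <- qr.coef(qx, Y)                      # (nP) x n
  B[is.na(B)] <- 0
  E <- Y - X %*% B
  sigma <- crossprod(E) / (length(idx) - n * P)
  A <- array(0, dim = c(P, n, n))
  for (r in seq_len(P))
    A[r, , ] <- t(B[(r - 1) * n + seq_len(n), , drop = FALSE])
  ld <- determinant(sigma, logarithm = TRUE)
  list(A = A, sigma = sigma, residuals = E,
       logdet_sigma = as.numeric(ld$modulus), n_eff = length(idx))
}

#' Select the MVAR model order by Schwarz's Bayesian criterion
#'
#' Fits stationary MVAR models over `p_min:p_max` on a common effective
#' sample (conditioning on `p_max` initial values) and returns the order
#' minimizing SBC.
#'
#' @param series Time x channel matrix or `tpdc_roits`.
#' @param p_min,p_max Order range (defaults 1 and 20).
#' @return Selected order (integer); the SBC values are attached as
#'   attribute `"sbc"`.
#' @export
select_model_order <- function(series, p_min = 1, p_max = 20) {
  y <- as_series_matrix(series)
  if (p_min > p_max) stop_tpdc("tpdc_parameter_error", "empty order range")
  n <- ncol(y); T_ <- nrow(y)
  if (T_ <= 10 * p_max)
    stop_tpdc("tpdc_parameter_error", "need more than 10 x p_max samples")
  orders <- p_min:p_max
  Ne <- T_ - p_max
  sbc <- vapply(orders, function(p) {
    # condition on the same p_max presample for comparability
    sub <- y[(p_max - p + 1):T_, , drop = FALSE]
    fit <- fit_mvar_ols(sub, p)
    fit$logdet_sigma + log(Ne) * p * n^2 / Ne
  }, numeric(1))
  out <- orders[which.min(sbc)]
  attr(out, "sbc") <- stats::setNames(sbc, orders)
  out
}

#' Fit a time-varying MVAR model by dual extended Kalman filtering
#'
#' Two coupled predictor-corrector filters are run in parallel over the
#' series: a state filter tracks the signal vector (predicting each sample
#' from the current coefficient estimates and correcting it against the
#' observation), and a weight filter tracks the stacked MVAR coefficients as
#' a random walk, using the state filter's estimates as its regressors. The
#' result is a coefficient trajectory `a_r(t)` for every sample after a
#' burn-in.
#'
#' All hyperparameters are explicit: `state_noise` is the random-walk
#' process-noise variance of the coefficient filter (default 1e-4),
#' `obs_noise` the per-channel observation-noise variance of the weight
#' filter (default: the innovation variance of a stationary least-squares
#' fit), and `init_scale` scales the initial weight covariance (identity).
#' Coefficients are initialized at the stationary least-squares solution
#' (`coef_init = "ols"`), so the filter tracks time variation around it;
#' haemodynamic-band series are slow relative to the filter memory, and a
#' cold start (`coef_init = "zero"`) may not finish converging within a
#' recording.
#'
#' @param series Zero-mean time x channel matrix or `tpdc_roits`.
#' @param P Model order (lags).
#' @param state_noise Process-noise variance of the coefficient random walk.
#' @param obs_noise Optional numeric vector of per-channel observation-noise
#'   variances; default is the innovation variance of the stationary fit.
#' @param init_scale Initial weight-covariance scale (default 0.01, a tight
#'   prior around the stationary solution).
#' @param coef_init `"ols"` (default) or `"zero"`.
#' @param burn_in Samples excluded from downstream averages
#'   (default `10 * P`).
#' @param fs Sampling rate (Hz), taken from `series` when available.
#' @return Object of class `tvmvar`: `coeffs` (array `T x P x n x n`),
#'   `order`, `noise_cov` (innovation covariance from one-step residuals),
#'   `residuals`, `fitted`, `burn_in`, `fs`, `series`.
#' @examples
#' net <- generate_network(n_rois = 3, edge_density = 0.3, seed = 2)
#' sim <- simulate_roi_timeseries(net, n_samples = 400, seed = 2)
#' fit <- tvmvar(sim$series, P = 1)
#' round(coef(fit), 2)
#' @export
tvmvar <- function(series, P, state_noise = 1e-4, obs_noise = NULL,
                   init_scale = 0.01, coef_init = c("ols", "zero"),
                   burn_in = NULL, fs = NULL) {
  y <- as_series_matrix(series)
  coef_init <- match.arg(coef_init)
  fs <- fs %||% attr(y, "fs") %||% 7.8125
  n <- ncol(y); T_ <- nrow(y)
  if (P < 1) stop_tpdc("tpdc_parameter_error", "P must be >= 1")
  if (T_ <= 10 * P * n)
    stop_tpdc("tpdc_parameter_error", "need more than 10 * P * n samples")
  y <- sweep(y, 2, colMeans(y))  # the model assumes zero-mean series
  burn_in <- burn_in %||% (10L * P)
  d <- n * P

  # stationary reference fit: warm start and innovation-scale obs noise
  ols <- fit_mvar_ols(y, P)
  if (coef_init == "ols") {
    W <- matrix(0, d, n)
    for (r in seq_len(P))
      W[(r - 1) * n + seq_len(n), ] <- t(ols$A[r, , ])
  } else {
    W <- matrix(0, d, n)
  }
  R <- obs_noise %||% pmax(diag(ols$sigma), 1e-12)
  R <- rep(R, length.out = n)
  if (any(R <= 0)) stop_tpdc("tpdc_parameter_error", "obs_noise must be positive")

  Pw <- lapply(seq_len(n), function(i) diag(init_scale, d))
  # state filter: tracks the signal with the current weights as dynamics;
  # its process noise is innovation-scale (the signal moves by one innovation
  # per step), its observation noise is small (clean measurements)
  xhat <- y
  Ps <- rep(init_scale, n)
  q_state <- R
  r_state <- 1e-4 * R
  coeffs <- array(0, dim = c(T_, P, n, n))
  resid <- matrix(0, T_, n)
  for (t in (P + 1):T_) {
    phi <- as.numeric(t(xhat[t - seq_len(P), , drop = FALSE]))  # lag-major: (lag r, channel j)
    # --- state filter: predict from current weights, correct on observation
    xpred <- as.numeric(crossprod(W, phi))
    Ps <- Ps + q_state
    Ks <- Ps / (Ps + r_state)
    xhat[t, ] <- xpred + Ks * (y[t, ] - xpred)
    Ps <- (1 - Ks) * Ps
    resid[t, ] <- y[t, ] - xpred
    # --- weight filter: random-walk coefficients, scalar measurement per target
    for (i in seq_len(n)) {
      Pi <- Pw[[i]]
      diag(Pi) <- diag(Pi) + state_noise
      Pphi <- Pi %*% phi
      S <- sum(phi * Pphi) + R[i]
      K <- Pphi / S
      W[, i] <- W[, i] + K * (y[t, i] - sum(phi * W[, i]))
      Pi <- Pi - tcrossprod(K, Pphi)
      Pw[[i]] <- Pi
    }
    if (!all(is.finite(W)) || any(vapply(Pw, function(p) !all(is.finite(p)), logical(1))))
      stop_tpdc("tpdc_numerical_error",
                "dual EKF diverged at sample %d (covariance blow-up)", t)
    # coeffs[t, r, i, j]: W rows are ordered (lag r, source j), columns target i
    coeffs[t, , , ] <- aperm(array(W, dim = c(n, P, n)), c(2, 3, 1))
  }
  keep <- (burn_in + 1):T_
  noise_cov <- crossprod(resid[keep, , drop = FALSE]) / length(keep)
  structure(list(coeffs = coeffs, order = as.integer(P), noise_cov = noise_cov,
                 residuals = resid, fitted = y - resid, burn_in = burn_in,
                 fs = fs, n_channels = n, series = y,
                 channel_names = colnames(y),
                 hyper = list(state_noise = state_noise, obs_noise = R,
                              init_scale = init_scale)),
            class = "tvmvar")
}

#' Extract coefficients from a time-varying MVAR fit
#'
#' @param object A `tvmvar`.
#' @param type `"average"` (post-burn-in time average, array `P x n x n`) or
#'   `"path"` (full `T x P x n x n` trajectory).
#' @param ... Unused.
#' @export
coef.tvmvar <- function(object, type = c("average", "path"), ...) {
  type <- match.arg(type)
  if (type == "path") return(object$coeffs)
  keep <- (object$burn_in + 1):dim(object$coeffs)[1]
  out <- apply(object$coeffs[keep, , , , drop = FALSE], c(2, 3, 4), mean)
  dimnames(out) <- list(paste0("lag", seq_len(object$order)),
                        object$channel_names, object$channel_names)
  out
}

#' @export
residuals.tvmvar <- function(object, ...) object$residuals

#' @export
fitted.tvmvar <- function(object, ...) object$fitted

#' One-step-ahead predictions from a time-varying MVAR fit
#'
#' Uses the final coefficient estimate to predict `n_ahead` steps beyond the
#' end of the series (iterated prediction).
#'
#' @param object A `tvmvar`.
#' @param n_ahead Steps ahead (default 1).
#' @param ... Unused.
#' @return Matrix `n_ahead x n` of predictions.
#' @export
predict.tvmvar <- function(object, n_ahead = 1, ...) {
  P <- object$order; n <- object$n_channels
  T_ <- nrow(object$series)
  A <- object$coeffs[T_, , , , drop = FALSE]
  hist <- object$series
  out <- matrix(0, n_ahead, n, dimnames = list(NULL, object$channel_names))
  for (h in seq_len(n_ahead)) {
    xt <- rep(0, n)
    for (r in seq_len(P)) {
      lagval <- if (h - r >= 1) out[h - r, ] else hist[T_ + h - r, ]
      xt <- xt + matrix(A[1, r, , ], n, n) %*% lagval
    }
    out[h, ] <- xt
  }
  out
}

#' Simulate from a fitted time-varying MVAR
#'
#' Draws new series from the post-burn-in time-averaged coefficients with
#' Gaussian innovations from the fitted innovation covariance.
#'
#' @param object A `tvmvar`.
#' @param nsim Number of samples to simulate.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix `nsim x n`.
#' @export
simulate.tvmvar <- function(object, nsim = nrow(object$series), seed = 0, ...) {
  A <- coef(object)
  P <- object$order; n <- object$n_channels
  L <- chol(object$noise_cov + diag(1e-12, n))
  with_seed(seed, {
    total <- nsim + 100
    x <- matrix(0, total, n)
    eta <- matrix(stats::rnorm(total * n), total, n) %*% L
    for (t in seq_len(total)) {
      xt <- eta[t, ]
      for (r in seq_len(min(P, t - 1)))
        xt <- xt + matrix(A[r, , ], n, n) %*% x[t - r, ]
      x[t, ] <- xt
    }
    out <- x[100 + seq_len(nsim), , drop = FALSE]
    colnames(out) <- object$channel_names
    out
  })
}

#' @export
print.tvmvar <- function(x, ...) {
  cat(sprintf("Time-varying MVAR (dual EKF): %d channels, order %d, %d samples (burn-in %d)\n",
              x$n_channels, x$order, nrow(x$series), x$burn_in))
  cat("Time-averaged coefficients (lag 1):\n")
  print(round(coef(x)[1, , ], 3))
  invisible(x)
}

#' @export
summary.tvmvar <- function(object, ...) {
  keep <- (object$burn_in + 1):dim(object$coeffs)[1]
  avg <- coef(object)
  sds <- apply(object$coeffs[keep, , , , drop = FALSE], c(2, 3, 4), stats::sd)
  structure(list(order = object$order, n_channels = object$n_channels,
                 n_samples = nrow(object$series), burn_in = object$burn_in,
                 coef_mean = avg, coef_sd = sds, noise_cov = object$noise_cov),
            class = "summary.tvmvar")
}

#' @export
print.summary.tvmvar <- function(x, ...) {
  cat(sprintf("Time-varying MVAR, order %d, %d channels, %d samples\n",
              x$order, x$n_channels, x$n_samples))
  for (r in seq_len(x$order)) {
    cat(sprintf("lag %d coefficient time-averages (SD of trajectory in brackets):\n", r))
    m <- matrix(sprintf("%.3f (%.3f)", x$coef_mean[r, , ], x$coef_sd[r, , ]),
                x$n_channels, x$n_channels,
                dimnames = dimnames(x$coef_mean)[2:3])
    print(m, quote = FALSE)
  }
  invisible(x)
}

#' Plot coefficient trajectories of a time-varying MVAR fit
#'
#' @param x A `tvmvar`.
#' @param lag Which lag to plot (default 1).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.tvmvar <- function(x, lag = 1, ...) {
  T_ <- dim(x$coeffs)[1]
  keep <- (x$burn_in + 1):T_
  n <- x$n_channels
  tr <- matrix(x$coeffs[keep, lag, , ], length(keep), n * n)
  graphics::matplot(keep / x$fs, tr, type = "l", lty = 1,
                    xlab = "time (s)", ylab = sprintf("a_%d(t)", lag),
                    main = sprintf("Dual-EKF coefficient trajectories, lag %d", lag), ...)
  invisible(x)
}
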