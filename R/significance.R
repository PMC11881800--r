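#' Bootstrap configuration for connection significance
#'
#' @param n_iterations Shuffle iterations (default 1000; use ~100-500 for
#'   quick runs, widening the Monte-Carlo tolerance accordingly).
#' @param n_windows Number `K` of nonoverlapping windows the series of
#'   length `N` is cut into (`N = K V`; trailing samples beyond the largest
#'   multiple are dropped). Must be at least 2 so that shuffling can permute.
#' @param percentile Null percentile used as the significance threshold
#'   (default 99).
#' @param seed Integer seed for the shuffles.
#' @return Object of class `tpdc_bootstrap_config`.
#' @export
bootstrap_config <- function(n_iterations = 1000, n_windows = 20,
                             percentile = 99, seed = 0) {
  if (n_windows < 2)
    stop_tpdc("tpdc_parameter_error", "shuffling requires at least 2 windows")
  if (percentile <= 0 || percentile >= 100)
    stop_tpdc("tpdc_parameter_error", "percentile must be in (0, 100)")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_windows = as.integer(n_windows),
                 percentile = percentile, seed = seed),
            class = "tpdc_bootstrap_config")
}

# internal: cut a time x n series into K windows and reorder them.
# perm may be a single permutation (applied to all channels jointly) or a
# K x n matrix of independent per-channel permutations; independent
# shuffling destroys cross-channel coupling while preserving each channel's
# within-window autocorrelation, which is the null the per-connection
# bootstrap requires.
shuffle_windows <- function(y, K, perm) {
  N <- nrow(y)
  V <- N %/% K
  use <- y[seq_len(K * V), , drop = FALSE]
  if (is.matrix(perm)) {
    out <- use
    for (ch in seq_len(ncol(use))) {
      idx <- as.vector(outer(seq_len(V), (perm[, ch] - 1) * V, `+`))
      out[, ch] <- use[idx, ch]
    }
    out
  } else {
    idx <- as.vector(outer(seq_len(V), (perm - 1) * V, `+`))
    use[idx, , drop = FALSE]
  }
}

#' Band-averaged directed connectivity statistic
#'
#' The statistic to which the bootstrap and time-reversal decisions are
#' applied. `method = "stationary"` fits a single least-squares MVAR and
#' band-averages its PDC (fast; the default for the shuffle null, matching
#' the stationary refit used for surrogates). `method = "dekf"` runs the
#' full time-varying estimator and band/time-averages. For valid inference
#' the same method must be (and is) applied to the observed series and to
#' every surrogate.
#'
#' @param series Time x channel matrix or `tpdc_roits`.
#' @param fs Sampling rate.
#' @param grid A [spectral_grid()].
#' @param order Fixed MVAR order.
#' @param method `"stationary"` or `"dekf"`.
#' @param ... Passed to [tpdc()] for the dekf method.
#' @return `n x n` matrix of band-averaged `|pi|` (diagonal `NA`).
#' @export
tpdc_statistic <- function(series, fs, grid, order,
                           method = c("stationary", "dekf"), ...) {
  method <- match.arg(method)
  if (method == "dekf") {
    res <- tpdc(series, fs = fs, grid = grid, order = order,
                check_stationarity = FALSE, ...)
    return(res$band_time_average)
  }
  y <- as_series_matrix(series)
  fit <- fit_mvar_ols(y, order)
  p <- pdc_from_coeffs(fit$A, grid$frequencies[grid$band_mask], grid$fs)
  m <- rowSums(p, dims = 2) / sum(grid$band_mask)
  dimnames(m) <- list(colnames(y), colnames(y))
  diag(m) <- NA_real_
  m
}

#' Windowed-shuffle bootstrap thresholds for TPDC significance
#'
#' For each iteration the series is cut into `K` nonoverlapping windows
#' whose order is randomly permuted, the connectivity statistic is
#' recomputed on the shuffled series, and the per-connection null
#' distribution is accumulated; the threshold is its `percentile`-th
#' (default 99th) percentile. The observed statistic is computed with the
#' identical statistic function, so under the null the declared-significant
#' rate matches the nominal tail mass.
#'
#' @param series Time x channel matrix or `tpdc_roits`.
#' @param config A [bootstrap_config()].
#' @param fs Sampling rate.
#' @param grid A [spectral_grid()]; default from `fs`.
#' @param order Fixed MVAR order (default 2).
#' @param method Statistic method, see [tpdc_statistic()].
#' @param ... Passed to [tpdc_statistic()].
#' @return Object of class `tpdc_bootstrap`: `observed`, `thresholds`
#'   (both `n x n`, diagonal `NA`), `significant_mask`, `null_values`
#'   (iterations x 42), `config`.
#' @export
bootstrap_threshold <- function(series, config = bootstrap_config(), fs = NULL,
                                grid = NULL, order = 2,
                                method = "stationary", ...) {
  y <- as_series_matrix(series)
  fs <- fs %||% attr(y, "fs") %||% 7.8125
  grid <- grid %||% spectral_grid(fs)
  K <- config$n_windows
  N <- nrow(y)
  V <- N %/% K
  if (V < 10 * order)
    stop_tpdc("tpdc_parameter_error",
              "windows too short: need N >= K * 10 * order")
  if (N %% K != 0)
    message(sprintf("truncating %d trailing sample(s) so that N = K x V", N %% K))
  n <- ncol(y)
  labels <- colnames(y)
  pairs <- connection_pairs(labels)
  observed <- tpdc_statistic(y, fs, grid, order, method = method, ...)
  nulls <- matrix(NA_real_, config$n_iterations, nrow(pairs))
  with_seed(config$seed, {
    for (b in seq_len(config$n_iterations)) {
      perm <- replicate(n, sample.int(K))
      stat <- tpdc_statistic(shuffle_windows(y, K, perm), fs, grid, order,
                             method = method, ...)
      nulls[b, ] <- stat[cbind(match(pairs$target, labels),
                               match(pairs$source, labels))]
    }
  })
  thr_vec <- apply(nulls, 2, stats::quantile, probs = config$percentile / 100,
                   names = FALSE)
  thresholds <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  thresholds[cbind(match(pairs$target, labels),
                   match(pairs$source, labels))] <- thr_vec
  mask <- observed > thresholds
  structure(list(observed = observed, thresholds = thresholds,
                 significant_mask = mask, null_values = nulls,
                 pairs = pairs, config = config, order = order,
                 method = method, grid = grid, fs = fs),
            class = "tpdc_bootstrap")
}

#' Time-reversal reliability test for directed connections
#'
#' A second significance test applied to bootstrap-significant connections:
#' genuinely lagged (causal) interactions invert their net direction when
#' the time axis is reversed, while instantaneous mixing artifacts (common
#' input, volume conduction) are direction-symmetric both forward and
#' reversed. The decision statistic for connection `j -> i` is the change in
#' directional asymmetry under reversal,
#' `D = (f[i,j] - f[j,i]) - (r[i,j] - r[j,i])`
#' with `f`/`r` the forward/reversed connectivity matrices; a connection
#' passes when `D` exceeds the null spread of the same statistic (its
#' `spread_percentile`-th percentile) over time-symmetrized surrogates:
#' windows are jointly permuted and each window is time-reversed with
#' probability 1/2 (all channels together), which preserves instantaneous
#' and symmetric lagged cross-correlation - the signature of mixing
#' artifacts - while destroying genuine directionality.
#'
#' @param series Time x channel matrix or `tpdc_roits`.
#' @param config A [bootstrap_config()]; its iterations are reused for the
#'   null spread.
#' @param selected Optional logical `n x n` mask of connections to test
#'   (e.g. the bootstrap `significant_mask`); untested connections cannot
#'   pass.
#' @param spread_percentile Percentile of the null `|forward - reversed|`
#'   spread (default 95).
#' @inheritParams bootstrap_threshold
#' @return Object of class `tpdc_trt`: `forward`, `reversed`, `spread`
#'   (`n x n`), `trt_mask`.
#' @export
time_reversal_test <- function(series, config = bootstrap_config(), fs = NULL,
                               grid = NULL, order = 2, selected = NULL,
                               spread_percentile = 95, method = "stationary", ...) {
  y <- as_series_matrix(series)
  fs <- fs %||% attr(y, "fs") %||% 7.8125
  grid <- grid %||% spectral_grid(fs)
  labels <- colnames(y)
  pairs <- connection_pairs(labels)
  n <- ncol(y)
  K <- config$n_windows
  asym <- function(m) {
    m0 <- m; m0[is.na(m0)] <- 0
    m0 - t(m0)
  }
  forward <- tpdc_statistic(y, fs, grid, order, method = method, ...)
  reversed <- tpdc_statistic(y[rev(seq_len(nrow(y))), , drop = FALSE],
                             fs, grid, order, method = method, ...)
  statistic <- asym(forward) - asym(reversed)
  diffs <- matrix(NA_real_, config$n_iterations, nrow(pairs))
  idx <- cbind(match(pairs$target, labels), match(pairs$source, labels))
  V <- nrow(y) %/% K
  with_seed(derive_seed(config$seed, "trt"), {
    for (b in seq_len(config$n_iterations)) {
      perm <- sample.int(K)
      flips <- stats::runif(K) < 0.5
      idxs <- unlist(lapply(seq_len(K), function(k) {
        win <- (perm[k] - 1) * V + seq_len(V)
        if (flips[k]) rev(win) else win
      }))
      ys <- y[idxs, , drop = FALSE]
      f <- tpdc_statistic(ys, fs, grid, order, method = method, ...)
      r <- tpdc_statistic(ys[rev(seq_len(nrow(ys))), , drop = FALSE],
                          fs, grid, order, method = method, ...)
      diffs[b, ] <- abs((asym(f) - asym(r))[idx])
    }
  })
  spread_vec <- apply(diffs, 2, stats::quantile,
                      probs = spread_percentile / 100, names = FALSE)
  spread <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  spread[idx] <- spread_vec
  mask <- statistic > spread
  if (!is.null(selected)) mask <- mask & selected
  structure(list(forward = forward, reversed = reversed, spread = spread,
                 statistic = statistic, trt_mask = mask, config = config),
            class = "tpdc_trt")
}

#' Combined bootstrap + time-reversal significance decision
#'
#' Runs [bootstrap_threshold()] and, on the bootstrap-significant
#' connections, [time_reversal_test()]; the final mask is their
#' conjunction.
#'
#' @inheritParams bootstrap_threshold
#' @param trt Logical; apply the time-reversal stage (default TRUE).
#' @return Object of class `tpdc_significance` with `observed`,
#'   `thresholds`, `significant_mask`, `trt_mask`, `final_mask`, and the 42-row
#'   `table` (`source`, `target`, `observed`, `threshold`, `bootstrap_pass`,
#'   `trt_pass`, `final`).
#' @export
significance_test <- function(series, config = bootstrap_config(), fs = NULL,
                              grid = NULL, order = 2, method = "stationary",
                              trt = TRUE, ...) {
  bt <- bootstrap_threshold(series, config, fs = fs, grid = grid,
                            order = order, method = method, ...)
  if (trt) {
    tr <- time_reversal_test(series, config, fs = bt$fs, grid = bt$grid,
                             order = order, selected = bt$significant_mask,
                             method = method, ...)
    trt_mask <- tr$trt_mask
  } else {
    tr <- NULL
    trt_mask <- bt$significant_mask
  }
  final <- bt$significant_mask & trt_mask
  labels <- rownames(bt$observed)
  pairs <- bt$pairs
  idx <- cbind(match(pairs$target, labels), match(pairs$source, labels))
  tab <- data.frame(source = pairs$source, target = pairs$target,
                    observed = bt$observed[idx],
                    threshold = bt$thresholds[idx],
                    bootstrap_pass = bt$significant_mask[idx],
                    trt_pass = trt_mask[idx],
                    final = final[idx],
                    stringsAsFactors = FALSE)
  structure(list(observed = bt$observed, thresholds = bt$thresholds,
                 significant_mask = bt$significant_mask, trt_mask = trt_mask,
                 final_mask = final, table = tab, bootstrap = bt, trt = tr,
                 config = config),
            class = "tpdc_significance")
}

#' @export
print.tpdc_significance <- function(x, ...) {
  cat(sprintf("Connection significance: %d of %d connections pass bootstrap, %d pass bootstrap + time reversal\n",
              sum(x$significant_mask, na.rm = TRUE), nrow(x$table),
              sum(x$final_mask, na.rm = TRUE)))
  invisible(x)
}

#' Summarize significance results across subjects
#'
#' @param results List of `tpdc_significance` objects (one per subject).
#' @return List with `table` (42 rows: `source`, `target`, `prevalence`,
#'   `mean_observed`) and `n_subjects`.
#' @export
summarize_connections <- function(results) {
  if (!length(results))
    stop_tpdc("tpdc_empty_error", "no subject results to summarize")
  tabs <- lapply(results, function(r) r$table)
  base <- tabs[[1]][, c("source", "target")]
  finals <- sapply(tabs, function(t) as.numeric(t$final))
  obs <- sapply(tabs, function(t) t$observed)
  base$prevalence <- rowMeans(finals)
  base$mean_observed <- rowMeans(obs)
  list(table = base, n_subjects = length(results))
}
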