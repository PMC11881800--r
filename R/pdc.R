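#' Spectral grid for PDC evaluation
#'
#' Evenly spaced frequencies spanning `(0, fs/2]` with a band mask for the
#' neurovascular-coupling band (default 0.009-0.08 Hz, chosen to avoid the
#' ~0.1 Hz Mayer-wave range). Band restriction is applied by averaging over
#' in-band grid points, never by pre-filtering the series.
#'
#' @param fs Sampling rate (Hz).
#' @param n_freq Number of grid points (default 64).
#' @param band Length-2 numeric, band endpoints in Hz.
#' @return Object of class `tpdc_grid`: `frequencies`, `band`, `band_mask`,
#'   `fs`.
#' @export
spectral_grid <- function(fs, n_freq = 64, band = c(0.009, 0.08)) {
  if (fs <= 0) stop_tpdc("tpdc_grid_error", "fs must be positive")
  band <- sort(band)
  if (band[2] >= fs / 2 || band[1] <= 0)
    stop_tpdc("tpdc_grid_error",
              "band (%.3g, %.3g) Hz must lie inside (0, fs/2 = %.3g) Hz",
              band[1], band[2], fs / 2)
  freqs <- seq(fs / 2 / n_freq, fs / 2, length.out = n_freq)
  mask <- freqs >= band[1] & freqs <= band[2]
  if (!any(mask))
    stop_tpdc("tpdc_grid_error",
              "no grid point falls in the band; increase n_freq")
  structure(list(frequencies = freqs, band = band, band_mask = mask, fs = fs),
            class = "tpdc_grid")
}

# internal: |pi|(i <- j) for one P x n x n coefficient array, all grid
# frequencies at once; returns n x n x F
pdc_from_coeffs <- function(A, freqs, fs) {
  P <- dim(A)[1]; n <- dim(A)[2]; F_ <- length(freqs)
  # E[r, f] = exp(-i 2 pi f r / fs)
  E <- exp(-1i * 2 * pi * outer(seq_len(P), freqs) / fs)
  Cm <- matrix(A, nrow = P)                 # P x (n*n), column-major (i fastest)
  Af <- -crossprod(Cm, E)                   # (n*n) x F: -sum_r a_r e^{-i w r}
  Af <- array(Af, dim = c(n, n, F_))
  for (k in seq_len(n)) Af[k, k, ] <- Af[k, k, ] + 1
  mag <- Mod(Af)
  denom <- sqrt(colSums(mag^2))              # per source column j and freq
  if (any(denom < 1e-300))
    stop_tpdc("tpdc_normalization_error", "degenerate all-zero column in A(lambda)")
  sweep(mag, c(2, 3), denom, "/")
}

#' Partial directed coherence spectrum at one time point
#'
#' Evaluates \eqn{\bar{A}(\lambda, t) = I - \sum_r a_r(t) e^{-i 2\pi\lambda r / f_s}}
#' and the column-normalized PDC
#' \eqn{|\pi_{i \leftarrow j}(\lambda)| = |\bar{A}_{ij}(\lambda)| /
#' \sqrt{\sum_k |\bar{A}_{kj}(\lambda)|^2}}, so that
#' \eqn{\sum_i |\pi_{i \leftarrow j}|^2 = 1} for every source column.
#'
#' @param model A `tvmvar` fit.
#' @param grid A [spectral_grid()].
#' @param t Sample index, after the model's burn-in.
#' @return Array `n x n x n_freq` of `|pi|` values in `[0, 1]`;
#'   `[i, j, f]` is the influence of channel j on channel i at frequency f.
#' @export
pdc_spectrum <- function(model, grid, t) {
  stopifnot(inherits(model, "tvmvar"), inherits(grid, "tpdc_grid"))
  T_ <- dim(model$coeffs)[1]
  if (t <= model$burn_in || t > T_)
    stop_tpdc("tpdc_parameter_error",
              "t must be in the post-burn-in range (%d, %d]", model$burn_in, T_)
  A <- array(model$coeffs[t, , , ], dim = dim(model$coeffs)[2:4])
  pdc_from_coeffs(A, grid$frequencies, grid$fs)
}

#' Temporal partial directed coherence of a multichannel series
#'
#' The full connectivity estimator: checks stationarity conditioning (ADF,
#' warning only), selects the MVAR order by SBC (or uses a fixed order),
#' fits the time-varying MVAR by dual extended Kalman filtering, evaluates
#' the PDC at every post-burn-in time point over the spectral grid, and
#' averages `|pi|` over in-band frequencies and time into a directed
#' `n x n` matrix (diagonal reported as `NA`).
#'
#' @param series `tpdc_roits` or time x channel matrix.
#' @param fs Sampling rate; taken from `series` when available.
#' @param grid A [spectral_grid()]; default built from `fs`.
#' @param order `"sbc"` for SBC selection (range `p_min:p_max`) or a fixed
#'   integer order.
#' @param p_min,p_max Order-selection range (defaults 1 and 5).
#' @param time_stride Evaluate the PDC every `time_stride`-th sample
#'   (default 1, every post-burn-in sample).
#' @param store_tensor Keep the full `target x source x freq x time` tensor
#'   (off by default; the band/time average is always returned).
#' @param check_stationarity Run per-channel ADF tests and warn on
#'   nonstationary channels (default TRUE).
#' @param ... Passed to [tvmvar()].
#' @return Object of class `tpdc_result`: `band_time_average` (n x n,
#'   `[i, j]` = influence of j on i, diagonal NA), `order`, `grid`,
#'   `model`, `labels`, optionally `tensor` with `times`.
#' @examples
#' net <- generate_network(n_rois = 3, edge_density = 0.4, seed = 5)
#' sim <- simulate_roi_timeseries(net, n_samples = 600, seed = 5)
#' res <- tpdc(sim$series, fs = sim$fs, order = 1)
#' round(res$band_time_average, 3)
#' @export
tpdc <- function(series, fs = NULL, grid = NULL, order = "sbc",
                 p_min = 1, p_max = 5, time_stride = 1,
                 store_tensor = FALSE, check_stationarity = TRUE, ...) {
  y <- as_series_matrix(series)
  fs <- fs %||% attr(y, "fs") %||% 7.8125
  grid <- grid %||% spectral_grid(fs)
  if (!inherits(grid, "tpdc_grid")) stop_tpdc("tpdc_grid_error", "grid must be a tpdc_grid")
  n <- ncol(y)
  if (check_stationarity) {
    ns <- vapply(seq_len(n), function(k)
      !adf_stationarity_test(y[, k])$reject_unit_root, logical(1))
    if (any(ns))
      warning("channel(s) ", paste(colnames(y)[ns], collapse = ", "),
              " look nonstationary (ADF failed to reject a unit root)")
  }
  P <- if (identical(order, "sbc")) as.integer(select_model_order(y, p_min, p_max))
       else as.integer(order)
  model <- tvmvar(y, P = P, fs = fs, ...)
  T_ <- nrow(y)
  times <- seq(model$burn_in + 1L, T_, by = as.integer(time_stride))
  F_ <- length(grid$frequencies)
  Pord <- model$order
  Ew <- exp(-1i * 2 * pi * outer(seq_len(Pord), grid$frequencies) / fs)

  acc <- matrix(0, n, n)
  tensor <- if (store_tensor) array(NA_real_, dim = c(n, n, F_, length(times)))
            else NULL
  # chunked vectorized evaluation over time
  chunk <- 256L
  for (blk in split(seq_along(times), ceiling(seq_along(times) / chunk))) {
    tt <- times[blk]
    # C: (n*n x P) per time -> stack as (length(tt)*n*n) x P
    Cm <- matrix(aperm(model$coeffs[tt, , , , drop = FALSE], c(3, 4, 1, 2)),
                 ncol = Pord)              # rows: (i, j, t), cols: lag
    Af <- -Cm %*% Ew                        # (n*n*length(tt)) x F
    Af <- array(Af, dim = c(n, n, length(tt), F_))
    for (k in seq_len(n)) Af[k, k, , ] <- Af[k, k, , ] + 1
    mag2 <- Mod(Af)^2
    denom <- sqrt(colSums(mag2))                  # n x length(tt) x F
    pi_abs <- sqrt(mag2) / rep(denom, each = n)
    if (store_tensor) tensor[, , , blk] <- aperm(pi_abs, c(1, 2, 4, 3))
    acc <- acc + rowSums(pi_abs[, , , grid$band_mask, drop = FALSE], dims = 2)
  }
  bta <- acc / (length(times) * sum(grid$band_mask))
  dimnames(bta) <- list(colnames(y), colnames(y))
  diag(bta) <- NA_real_
  structure(list(band_time_average = bta, order = P, grid = grid,
                 model = model, labels = colnames(y),
                 tensor = tensor, times = if (store_tensor) times else NULL),
            class = "tpdc_result")
}

#' Average left- and right-hemisphere connectivity results
#'
#' Element-wise mean of the band/time-averaged directed matrices (and of the
#' tensors when both carry one). ROI ordering and grids must agree.
#'
#' @param left,right `tpdc_result` objects.
#' @return A `tpdc_result` with averaged matrices.
#' @export
average_hemispheres <- function(left, right) {
  stopifnot(inherits(left, "tpdc_result"), inherits(right, "tpdc_result"))
  if (!identical(left$labels, right$labels))
    stop_tpdc("tpdc_schema_error", "ROI sets differ between hemispheres")
  if (!isTRUE(all.equal(left$grid$frequencies, right$grid$frequencies)))
    stop_tpdc("tpdc_schema_error", "spectral grids differ between hemispheres")
  out <- left
  out$band_time_average <- (left$band_time_average + right$band_time_average) / 2
  if (!is.null(left$tensor) && !is.null(right$tensor) &&
      identical(dim(left$tensor), dim(right$tensor)))
    out$tensor <- (left$tensor + right$tensor) / 2
  out$hemisphere <- "averaged"
  out
}

#' Connection table of a TPDC result
#'
#' @param result A `tpdc_result` (or plain directed matrix).
#' @return Data frame with 42 rows (for 7 ROIs): `source`, `target`, `value`.
#' @export
connection_table <- function(result) {
  m <- if (inherits(result, "tpdc_result")) result$band_time_average else as.matrix(result)
  labels <- rownames(m) %||% paste0("roi", seq_len(nrow(m)))
  pairs <- connection_pairs(labels)
  pairs$value <- m[cbind(match(pairs$target, labels), match(pairs$source, labels))]
  pairs
}

#' @export
print.tpdc_result <- function(x, ...) {
  cat(sprintf("TPDC result: %d ROIs, order %d, band %.3g-%.3g Hz%s\n",
              length(x$labels), x$order, x$grid$band[1], x$grid$band[2],
              if (!is.null(x$hemisphere)) paste0(" (", x$hemisphere, ")") else ""))
  cat("Band/time-averaged directed connectivity (row = target, col = source):\n")
  print(round(x$band_time_average, 3))
  invisible(x)
}

#' Plot a TPDC connectivity matrix
#'
#' @param x A `tpdc_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tpdc_result <- function(x, ...) {
  m <- x$band_time_average
  m[is.na(m)] <- 0
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m)[, n:1], axes = FALSE,
                  xlab = "source", ylab = "target",
                  main = "Band/time-averaged TPDC", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m))
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)))
  invisible(x)
}
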