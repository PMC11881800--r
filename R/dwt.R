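# Periodized orthogonal discrete wavelet transform (haar / db2).
# Written in-package because the motion-correction wavelet stage needs only a
# plain pyramid DWT with perfect reconstruction; round-trip accuracy is
# asserted in the test suite.

dwt_filter <- function(family) {
  h <- switch(family,
              haar = c(1, 1) / sqrt(2),
              db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
              stop_tpdc("tpdc_parameter_error", "unknown wavelet family '%s'", family))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, L = L)
}

# one analysis level on a vector of even length (periodic boundary)
dwt_step <- function(x, filt) {
  N <- length(x); half <- N / 2
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(filt$L)) {
    idx <- ((2 * (seq_len(half) - 1) + m - 1) %% N) + 1
    a <- a + filt$h[m] * x[idx]
    d <- d + filt$g[m] * x[idx]
  }
  list(a = a, d = d)
}

# adjoint (= inverse, orthonormal basis) of dwt_step
idwt_step <- function(a, d, filt) {
  half <- length(a); N <- 2 * half
  x <- numeric(N)
  for (m in seq_len(filt$L)) {
    idx <- ((2 * (seq_len(half) - 1) + m - 1) %% N) + 1
    contrib <- filt$h[m] * a + filt$g[m] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Periodized discrete wavelet transform
#'
#' Pyramid analysis of a numeric vector whose length must be divisible by
#' `2^levels`. Orthonormal (periodized) filters, so [idwt()] reconstructs to
#' machine precision.
#'
#' @param x Numeric vector.
#' @param family `"db2"` (default) or `"haar"`.
#' @param levels Decomposition depth.
#' @return List with `approx` (coarsest approximation), `details` (list,
#'   finest level first), `family`, `levels`.
#' @export
dwt <- function(x, family = "db2", levels = 4) {
  filt <- dwt_filter(family)
  if (length(x) %% 2^levels != 0)
    stop_tpdc("tpdc_parameter_error",
              "length must be divisible by 2^levels (got %d)", length(x))
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, filt)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, family = family, levels = levels)
}

#' Inverse periodized discrete wavelet transform
#' @param w Result of [dwt()].
#' @return Reconstructed numeric vector.
#' @export
idwt <- function(w) {
  filt <- dwt_filter(w$family)
  a <- w$approx
  for (j in rev(seq_len(w$levels))) a <- idwt_step(a, w$details[[j]], filt)
  a
}

# internal: zero detail coefficients whose standardized magnitude falls in
# the outer alpha tail of a Gaussian fit (robust location/scale)
wavelet_despike <- function(x, family = "db2", levels = 4, alpha = 0.1) {
  n <- length(x)
  block <- 2^levels
  pad <- (block - n %% block) %% block
  xe <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  w <- dwt(xe, family = family, levels = levels)
  zcut <- stats::qnorm(1 - alpha / 2)
  for (j in seq_len(levels)) {
    d <- w$details[[j]]
    s <- stats::mad(d)
    if (s > 0) {
      z <- (d - stats::median(d)) / s
      d[abs(z) > zcut] <- 0
      w$details[[j]] <- d
    }
  }
  idwt(w)[seq_len(n)]
}
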