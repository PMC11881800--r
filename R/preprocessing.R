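#' Convert raw intensities to delta optical density
#'
#' Per channel and wavelength,
#' \deqn{\Delta OD(t) = \ln\left[\Phi_{ref} / \Phi(t)\right]}
#' where the reference intensity is the channel's temporal mean by default
#' (robust to startup transients; set `reference = "first"` for the literal
#' first sample).
#'
#' @param recording A `tpdc_recording` (see [synthesize_raw_recording()] and
#'   [read_recording()]).
#' @param reference `"mean"` (default) or `"first"`.
#' @return Object of class `tpdc_od` carrying `delta_od`
#'   (`channel-row x time`), the channel table and acquisition metadata.
#' @export
intensity_to_od <- function(recording, reference = c("mean", "first")) {
  reference <- match.arg(reference)
  phi <- recording$intensities
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    bad <- which(!is.finite(phi) | phi <= 0, arr.ind = TRUE)[1, ]
    stop_tpdc("tpdc_domain_error",
              "nonpositive intensity at channel row %d, sample %d", bad[1], bad[2])
  }
  ref <- if (reference == "mean") rowMeans(phi) else phi[, 1]
  dod <- log(ref / phi)
  structure(list(delta_od = dod, channels = recording$channels,
                 fs = recording$fs, age = recording$age,
                 distance_cm = recording$distance_cm %||% 3,
                 reference = reference),
            class = "tpdc_od")
}

#' Detect motion artifacts by moving statistics
#'
#' Flags samples where the moving standard deviation of the channel's fast
#' component (signal minus a running median) exceeds `sd_thresh` reference
#' SDs, where its pointwise amplitude exceeds `amp_thresh` reference SDs,
#' or where the first difference jumps by more than `amp_thresh` reference
#' SDs (baseline steps are invisible to the running-median component and
#' are caught by the derivative criterion). The reference SD is a robust
#' (MAD-based) scale floored at 10% of the channel SD, so smooth
#' high-amplitude physiology is not flagged; flags are dilated by two
#' samples to cover artifact tails.
#'
#' @param x Numeric vector (one channel of delta OD).
#' @param fs Sampling rate (Hz).
#' @param window_s Detection window in seconds (default 1).
#' @param sd_thresh,amp_thresh Thresholds in reference-SD units
#'   (defaults 13.5 and 5).
#' @return Logical vector of flagged samples.
#' @export
detect_motion <- function(x, fs, window_s = 1, sd_thresh = 13.5, amp_thresh = 5) {
  n <- length(x)
  w <- max(2L, as.integer(round(window_s * fs)))
  if (w > n) stop_tpdc("tpdc_parameter_error", "window longer than recording")
  k <- min(2L * w + 1L, if (n %% 2 == 0) n - 1L else n)
  if (k %% 2 == 0) k <- k - 1L
  fast <- x - stats::runmed(x, k)
  sref <- max(stats::mad(fast), 0.1 * stats::sd(x), 1e-300)
  flags <- logical(n)
  half <- w %/% 2
  # moving SD of the fast component plus a pointwise amplitude criterion
  cs <- cumsum(c(0, fast)); cs2 <- cumsum(c(0, fast^2))
  for (t in seq_len(n)) {
    lo <- max(1, t - half); hi <- min(n, t + half)
    m <- hi - lo + 1
    mu <- (cs[hi + 1] - cs[lo]) / m
    v <- max((cs2[hi + 1] - cs2[lo]) / m - mu^2, 0)
    if (sqrt(v) > sd_thresh * sref) flags[t] <- TRUE
  }
  flags <- flags | abs(fast - stats::median(fast)) > amp_thresh * sref
  # first-difference criterion catches baseline jumps the running median follows
  d <- c(0, diff(x))
  sref_d <- max(stats::mad(d), 0.1 * stats::sd(x), 1e-300)
  flags <- flags | abs(d) > amp_thresh * sref_d
  # dilate flags so artifact tails are covered
  if (any(flags)) {
    idx <- which(flags)
    grow <- unique(pmin(pmax(rep(idx, each = 5) + (-2):2, 1L), n))
    flags[grow] <- TRUE
  }
  flags
}

# internal: correct one channel given flagged samples. Baseline shifts are
# rejoined first (a step's net level change across the segment, measured
# from clean neighbours, is removed from everything after it; a spike's
# jumps cancel, so spikes are never rejoined), then each flagged segment is
# replaced by a spline prediction from the surrounding clean data.
spline_correct_channel <- function(x, flags, fs, spline_spar = 0.5,
                                   amp_thresh = 5) {
  n <- length(x)
  if (!any(flags)) return(x)
  d <- c(0, diff(x))
  sref_d <- max(stats::mad(d), 1e-300)
  r <- rle(flags)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  w <- max(2L, as.integer(round(fs)))
  for (seg in which(r$values)) {
    lo <- starts[seg]; hi <- ends[seg]
    # step signature: net level change across the segment comparable to the
    # largest single jump inside it; spikes return to baseline (net ~ 0)
    delta <- if (lo > 1 && hi < n) x[hi + 1] - x[lo - 1] else 0
    jump <- d[lo:hi][abs(d[lo:hi]) > amp_thresh * sref_d]
    if (hi < n && length(jump) && abs(delta) > amp_thresh * sref_d &&
        abs(delta) > 0.6 * max(abs(jump)))
      x[(hi + 1):n] <- x[(hi + 1):n] - delta
    # replace the segment by a spline fit of the clean neighbourhood
    nb <- c(max(1, lo - 2 * w):max(1, lo - 1),
            min(n, hi + 1):min(n, hi + 2 * w))
    nb <- setdiff(unique(nb), lo:hi)
    if (length(nb) >= 8) {
      fit <- try(stats::smooth.spline(nb, x[nb], spar = spline_spar),
                 silent = TRUE)
      x[lo:hi] <- if (inherits(fit, "try-error"))
        stats::approx(nb, x[nb], xout = lo:hi, rule = 2)$y
      else stats::predict(fit, lo:hi)$y
    } else if (length(nb) >= 2) {
      x[lo:hi] <- stats::approx(nb, x[nb], xout = lo:hi, rule = 2)$y
    }
  }
  x
}

#' Motion-correct optical density series
#'
#' Two stages, per channel: (1) moving-SD/amplitude detection followed by
#' spline correction of flagged segments with baseline rejoining; (2) wavelet
#' artifact correction that zeroes detail coefficients whose standardized
#' magnitude lies in the outer `wavelet_alpha` tail of a Gaussian fit.
#' Artifact-free input passes through the spline stage unchanged.
#'
#' @param od A `tpdc_od`.
#' @param window_s,sd_thresh,amp_thresh Detection parameters, see
#'   [detect_motion()].
#' @param spline_spar Smoothing parameter of the segment spline refit.
#' @param wavelet_alpha Gaussian tail probability for the wavelet stage
#'   (default 0.1); `NA` skips the wavelet stage.
#' @param wavelet,wavelet_levels Wavelet family and depth (db2, 4 levels).
#' @return A `tpdc_od` with corrected series; flagged-sample counts are kept
#'   in `$motion_flags`.
#' @export
correct_motion <- function(od, window_s = 1, sd_thresh = 13.5, amp_thresh = 5,
                           spline_spar = 0.5, wavelet_alpha = 0.1,
                           wavelet = "db2", wavelet_levels = 4) {
  stopifnot(inherits(od, "tpdc_od"))
  x <- od$delta_od
  n <- ncol(x)
  w <- as.integer(round(window_s * od$fs))
  if (w < 2) stop_tpdc("tpdc_parameter_error", "window_s x fs must be >= 2 samples")
  if (w > n) stop_tpdc("tpdc_parameter_error", "window longer than recording")
  flags <- matrix(FALSE, nrow(x), n)
  for (ch in seq_len(nrow(x))) {
    f <- detect_motion(x[ch, ], od$fs, window_s, sd_thresh, amp_thresh)
    flags[ch, ] <- f
    x[ch, ] <- spline_correct_channel(x[ch, ], f, od$fs, spline_spar)
    if (!is.na(wavelet_alpha))
      x[ch, ] <- wavelet_despike(x[ch, ], family = wavelet,
                                 levels = wavelet_levels, alpha = wavelet_alpha)
  }
  out <- od
  out$delta_od <- x
  out$motion_flags <- flags
  out
}

#' Convert optical density to haemoglobin concentrations
#'
#' Modified Beer-Lambert law: for each source-detector pair the two-wavelength
#' delta OD vector is inverted through the extinction matrix scaled by the
#' source-detector distance and the age-dependent DPF
#' (`4.99 + 0.067 * age^0.814`), yielding relative HbO and HbR concentrations
#' in microM.
#'
#' @param od A `tpdc_od`.
#' @param age_years Age driving the DPF; defaults to the recording's age.
#' @param distance_cm Source-detector separation (default from recording, 3 cm).
#' @param extinction Extinction table, see [extinction_table()].
#' @return Object of class `tpdc_hb` with `hbo`, `hbr`
#'   (`n_pairs x time`, microM), a per-pair `pairs` table, `fs`, `dpf`.
#' @export
od_to_hemoglobin <- function(od, age_years = NULL, distance_cm = NULL,
                             extinction = extinction_table()) {
  stopifnot(inherits(od, "tpdc_od"))
  age_years <- age_years %||% od$age
  distance_cm <- distance_cm %||% od$distance_cm
  if (is.null(age_years) || age_years < 0)
    stop_tpdc("tpdc_parameter_error", "age must be given and >= 0")
  ch <- od$channels
  pair_ids <- unique(ch$channel)
  d <- dpf(age_years)
  hbo <- matrix(0, length(pair_ids), ncol(od$delta_od))
  hbr <- hbo
  for (k in seq_along(pair_ids)) {
    rows <- which(ch$channel == pair_ids[k])
    wl <- ch$wavelength[rows]
    if (length(rows) != 2 || length(unique(wl)) != 2)
      stop_tpdc("tpdc_pairing_error",
                "channel %s lacks a two-wavelength pair", pair_ids[k])
    E <- extinction_matrix(wl, extinction) * distance_cm * d
    conc <- solve(E, od$delta_od[rows, , drop = FALSE])
    hbo[k, ] <- conc[1, ]
    hbr[k, ] <- conc[2, ]
  }
  pairs <- ch[match(pair_ids, ch$channel), c("channel", "source", "detector")]
  rownames(pairs) <- NULL
  structure(list(hbo = hbo, hbr = hbr, pairs = pairs, fs = od$fs,
                 dpf = d, distance_cm = distance_cm, age = age_years),
            class = "tpdc_hb")
}

#' Linearly detrend and zero-centre haemoglobin series
#'
#' Removes the per-channel least-squares line and centres each channel to
#' zero mean, the stationarity conditioning applied before connectivity
#' estimation. No band-pass filtering is applied at any point of the
#' pipeline. Constant channels are set to zero and recorded in
#' `$constant_channels`.
#'
#' @param hb A `tpdc_hb`.
#' @return A `tpdc_hb` with detrended, zero-mean channels.
#' @export
detrend_center <- function(hb) {
  stopifnot(inherits(hb, "tpdc_hb"))
  n <- ncol(hb$hbo)
  if (n < 3) stop_tpdc("tpdc_parameter_error", "need at least 3 samples")
  tt <- seq_len(n)
  X <- cbind(1, tt)
  XtXi <- solve(crossprod(X))
  const <- integer(0)
  detrend <- function(M) {
    for (chn in seq_len(nrow(M))) {
      y <- M[chn, ]
      if (stats::sd(y) == 0) {
        M[chn, ] <- 0
        const <<- c(const, chn)
      } else {
        beta <- XtXi %*% crossprod(X, y)
        M[chn, ] <- y - as.numeric(X %*% beta)
      }
    }
    M
  }
  hb$hbo <- detrend(hb$hbo)
  hb$hbr <- detrend(hb$hbr)
  if (length(const)) {
    warning("constant channel(s) set to zero: ", paste(unique(const), collapse = ", "))
    hb$constant_channels <- unique(const)
  }
  hb
}

#' Remove the shared systemic component by spatial-domain regression
#'
#' For each chromophore a cross-channel summary time course (the estimated
#' nonneural systemic component, standing in for short-separation channels)
#' is regressed out of every channel; residuals are orthogonal to the
#' regressor. The default summary is the cross-channel median, which is
#' robust against the focal neural signal leaking into the regressor when
#' only a minority of channels overlie the network of interest; the plain
#' cross-channel mean is available via `estimator = "mean"`. When
#' `channels` names a set of background channels (e.g. montage channels
#' outside the region-of-interest map), the regressor is estimated from
#' those channels only, which keeps the neural signal out of the regressor
#' entirely. With a single channel this is a no-op with a warning.
#'
#' @param hb A `tpdc_hb`.
#' @param estimator `"median"` (default) or `"mean"`.
#' @param channels Optional vector of channel ids (matching
#'   `hb$pairs$channel`) from which to estimate the systemic regressor;
#'   default: all channels.
#' @return A `tpdc_hb` of residual series.
#' @export
remove_systemic <- function(hb, estimator = c("median", "mean"), channels = NULL) {
  stopifnot(inherits(hb, "tpdc_hb"))
  estimator <- match.arg(estimator)
  if (nrow(hb$hbo) < 2) {
    warning("single channel: systemic regression skipped")
    return(hb)
  }
  rows <- if (is.null(channels)) seq_len(nrow(hb$hbo))
          else match(channels, hb$pairs$channel)
  if (anyNA(rows))
    stop_tpdc("tpdc_parameter_error", "unknown channel id(s) in 'channels'")
  strip <- function(M) {
    sub <- M[rows, , drop = FALSE]
    g <- if (estimator == "median") apply(sub, 2, stats::median) else colMeans(sub)
    X <- cbind(1, g)
    if (stats::sd(g) == 0) return(sweep(M, 2, mean(g)))
    XtXi <- solve(crossprod(X))
    for (chn in seq_len(nrow(M))) {
      beta <- XtXi %*% crossprod(X, M[chn, ])
      M[chn, ] <- M[chn, ] - as.numeric(X %*% beta)
    }
    M
  }
  hb$hbo <- strip(hb$hbo)
  hb$hbr <- strip(hb$hbr)
  hb
}

#' Pool channels into region-of-interest time series
#'
#' Averages the member channels of each of the 7 reading-network ROIs,
#' separately per hemisphere. Channels outside the map are dropped; the
#' number retained is reported in the result.
#'
#' @param hb A `tpdc_hb`.
#' @param roi_map Data frame `channel`, `roi`, `hemisphere`
#'   (default [default_roi_map()]).
#' @param chromophore `"hbo"` (default) or `"hbr"`.
#' @return Named list of `tpdc_roits` objects (one per hemisphere), each with
#'   `series` (`roi x time`), `roi_labels`, `hemisphere`, `chromophore`,
#'   `fs`, `n_channels_retained`.
#' @export
pool_rois <- function(hb, roi_map = default_roi_map(), chromophore = c("hbo", "hbr")) {
  stopifnot(inherits(hb, "tpdc_hb"))
  chromophore <- match.arg(chromophore)
  validate_roi_map(roi_map, hb$pairs$channel)
  M <- hb[[chromophore]]
  out <- list()
  for (h in unique(roi_map$hemisphere)) {
    sub <- roi_map[roi_map$hemisphere == h, ]
    series <- matrix(0, length(roi_labels()), ncol(M),
                     dimnames = list(roi_labels(), NULL))
    for (roi in roi_labels()) {
      chans <- sub$channel[sub$roi == roi]
      rows <- match(chans, hb$pairs$channel)
      series[roi, ] <- colMeans(M[rows, , drop = FALSE])
    }
    out[[h]] <- structure(list(series = series, roi_labels = roi_labels(),
                               hemisphere = h, chromophore = chromophore,
                               fs = hb$fs, n_channels_retained = nrow(sub)),
                          class = "tpdc_roits")
  }
  attr(out, "n_channels_retained") <- sum(roi_map$channel %in% hb$pairs$channel)
  out
}

#' @export
print.tpdc_roits <- function(x, ...) {
  cat(sprintf("ROI time series (%s, %s hemisphere): %d ROIs x %d samples at %.4g Hz\n",
              x$chromophore, x$hemisphere, nrow(x$series), ncol(x$series), x$fs))
  invisible(x)
}

#' Run the full preprocessing chain on a raw recording
#'
#' Intensity to delta OD, motion correction (spline + wavelet), modified
#' Beer-Lambert conversion, linear detrend and zero-centreing, spatial-domain
#' systemic regression, and ROI pooling per hemisphere.
#'
#' @param recording A `tpdc_recording`.
#' @param roi_map Channel-to-ROI map.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param correct Logical; run the motion-correction stage (default TRUE).
#' @param ... Passed to [correct_motion()].
#' @return List of per-hemisphere `tpdc_roits` objects.
#' @export
preprocess_recording <- function(recording, roi_map = default_roi_map(),
                                 chromophore = "hbo", correct = TRUE, ...) {
  od <- intensity_to_od(recording)
  if (correct) od <- correct_motion(od, ...)
  hb <- od_to_hemoglobin(od)
  hb <- detrend_center(hb)
  # systemic regressor from the montage channels outside the network of
  # interest (spatial-domain filtering); all-channel median if none exist
  background <- setdiff(hb$pairs$channel, roi_map$channel)
  hb <- if (length(background) >= 8)
    remove_systemic(hb, estimator = "mean", channels = background)
  else remove_systemic(hb)
  pool_rois(hb, roi_map = roi_map, chromophore = chromophore)
}
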