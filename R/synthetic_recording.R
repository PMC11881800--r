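#' Artifact specification for synthetic recordings
#'
#' Describes the confounds injected into synthetic channel data: motion
#' spikes and baseline shifts, a shared Mayer-wave oscillation near 0.1 Hz,
#' and a shared low-frequency systemic component. These emulate the nuisance
#' structure the preprocessing stages are designed to remove.
#'
#' @param spike_rate Motion spikes per minute per channel.
#' @param spike_amplitude Spike peak, in multiples of the channel's
#'   artifact-free signal SD.
#' @param shift_rate Baseline shifts per minute per channel.
#' @param shift_amplitude Shift size, in multiples of the signal SD.
#' @param mayer_amplitude Relative amplitude of the ~0.1 Hz Mayer oscillation
#'   (shared across channels, channel-specific gain).
#' @param global_systemic_amplitude Relative amplitude of the shared
#'   low-frequency systemic component.
#' @return Object of class `tpdc_artifact_spec`.
#' @export
artifact_spec <- function(spike_rate = 0.3, spike_amplitude = 12,
                          shift_rate = 0.1, shift_amplitude = 6,
                          mayer_amplitude = 0.4, global_systemic_amplitude = 0.5) {
  vals <- c(spike_rate, spike_amplitude, shift_rate, shift_amplitude,
            mayer_amplitude, global_systemic_amplitude)
  if (any(vals < 0))
    stop_tpdc("tpdc_parameter_error", "artifact rates and amplitudes must be >= 0")
  structure(list(spike_rate = spike_rate, spike_amplitude = spike_amplitude,
                 shift_rate = shift_rate, shift_amplitude = shift_amplitude,
                 mayer_amplitude = mayer_amplitude,
                 global_systemic_amplitude = global_systemic_amplitude),
            class = "tpdc_artifact_spec")
}

#' Synthesize a raw two-wavelength fNIRS recording
#'
#' Forward model for the whole preprocessing chain: each mapped channel's
#' oxyhaemoglobin trace is its ROI's latent series (unit-variance, scaled to
#' `amplitude_um` microM) plus channel noise, shared systemic and Mayer
#' components, and injected spikes/shifts; deoxyhaemoglobin is an
#' anticorrelated scaled copy with its own noise. The modified Beer-Lambert
#' law with the age-dependent DPF then maps chromophores to optical density,
#' and intensities are `baseline * exp(-dOD)` per wavelength, so they are
#' strictly positive.
#'
#' @param roi_series Result of [simulate_roi_timeseries()], or a plain
#'   `time x roi` matrix.
#' @param montage Data frame from [default_montage()].
#' @param roi_map Data frame from [default_roi_map()].
#' @param age Subject age in years (drives the DPF).
#' @param artifacts An [artifact_spec()]; use rates/amplitudes of 0 for a
#'   clean recording.
#' @param channel_noise_sd Channel-local noise SD relative to signal SD.
#' @param amplitude_um Haemodynamic signal amplitude in microM.
#' @param hbr_ratio HbR = `-hbr_ratio` * HbO (neurovascular anticorrelation).
#' @param baseline Reference light intensity (device units, `> 0`).
#' @param distance_cm Source-detector separation in cm.
#' @param fs Sampling rate; taken from `roi_series` when available.
#' @param seed Integer seed.
#' @return Object of class `tpdc_recording`: `intensities`
#'   (`(2 * n_pairs) x time`, rows alternate 760/850 nm per pair), `channels`
#'   (data frame `row`, `channel`, `source`, `detector`, `wavelength`), `fs`,
#'   `age`, `distance_cm`, `baseline`, plus ground truth `truth_hbo`,
#'   `truth_hbr` (`n_pairs x time`, microM) and injected artifact indices.
#' @export
synthesize_raw_recording <- function(roi_series, montage = default_montage(),
                                     roi_map = default_roi_map(), age = 10,
                                     artifacts = artifact_spec(),
                                     channel_noise_sd = 0.2, amplitude_um = 0.5,
                                     hbr_ratio = 0.4, baseline = 1000,
                                     distance_cm = 3, fs = NULL, seed = 0) {
  if (is.list(roi_series) && !is.null(roi_series$series)) {
    fs <- fs %||% roi_series$fs
    latent <- roi_series$series
  } else latent <- as.matrix(roi_series)
  fs <- fs %||% 7.8125
  if (age < 0) stop_tpdc("tpdc_parameter_error", "age must be >= 0")
  if (baseline <= 0)
    stop_tpdc("tpdc_parameter_error", "baseline intensity must be positive")
  validate_roi_map(roi_map, montage$channel)
  if (is.null(colnames(latent)))
    colnames(latent) <- paste0("roi", seq_len(ncol(latent)))
  bad <- setdiff(unique(roi_map$roi), colnames(latent))
  if (length(bad) && all(roi_labels() %in% colnames(latent)) == FALSE)
    stop_tpdc("tpdc_mapping_error", "latent series lacks ROI(s) %s",
              paste(bad, collapse = ", "))

  T_ <- nrow(latent); np <- nrow(montage)
  tgrid <- (seq_len(T_) - 1) / fs
  # unit-variance latent per ROI (constant columns stay zero)
  lz <- apply(latent, 2, function(col) {
    col <- col - mean(col); s <- stats::sd(col)
    if (s > 0) col / s else col
  })
  colnames(lz) <- colnames(latent)
  with_seed(seed, {
    systemic <- as.numeric(stats::filter(stats::rnorm(T_), rep(1 / 15, 15), sides = 1))
    systemic[is.na(systemic)] <- 0
    systemic <- if (stats::sd(systemic) > 0) systemic / stats::sd(systemic) else systemic
    mayer <- sin(2 * pi * 0.1 * tgrid + stats::runif(1, 0, 2 * pi))

    hbo <- matrix(0, np, T_); hbr <- matrix(0, np, T_)
    spike_idx <- vector("list", np); shift_idx <- vector("list", np)
    minutes <- T_ / fs / 60
    for (p in seq_len(np)) {
      m <- match(montage$channel[p], roi_map$channel)
      sig <- if (!is.na(m)) lz[, roi_map$roi[m]] else rep(0, T_)
      g_sys <- artifacts$global_systemic_amplitude * stats::runif(1, 0.85, 1.15)
      g_may <- artifacts$mayer_amplitude * stats::runif(1, 0.85, 1.15)
      x <- sig + channel_noise_sd * stats::rnorm(T_) + g_sys * systemic + g_may * mayer
      ref_sd <- max(stats::sd(x), 1e-12)
      n_sp <- stats::rpois(1, artifacts$spike_rate * minutes)
      if (n_sp > 0 && artifacts$spike_amplitude > 0) {
        idx <- sort(sample.int(T_, n_sp))
        for (i0 in idx) {
          len <- min(T_ - i0 + 1, 5L)
          x[i0 + seq_len(len) - 1] <- x[i0 + seq_len(len) - 1] +
            artifacts$spike_amplitude * ref_sd * exp(-(seq_len(len) - 1))
        }
        spike_idx[[p]] <- idx
      }
      n_sh <- stats::rpois(1, artifacts$shift_rate * minutes)
      if (n_sh > 0 && artifacts$shift_amplitude > 0) {
        idx <- sort(sample.int(T_ - 1, n_sh)) + 1L
        for (i0 in idx) x[i0:T_] <- x[i0:T_] +
            artifacts$shift_amplitude * ref_sd * sample(c(-1, 1), 1)
        shift_idx[[p]] <- idx
      }
      hbo[p, ] <- amplitude_um * x
      hbr[p, ] <- -hbr_ratio * amplitude_um * x +
        0.3 * channel_noise_sd * amplitude_um * stats::rnorm(T_)
    }

    E <- extinction_matrix(c(760, 850)) * distance_cm * dpf(age)
    intens <- matrix(0, 2 * np, T_)
    channels <- data.frame(row = seq_len(2 * np),
                           channel = rep(montage$channel, each = 2),
                           source = rep(montage$source, each = 2),
                           detector = rep(montage$detector, each = 2),
                           wavelength = rep(c(760, 850), np))
    for (p in seq_len(np)) {
      dod <- E %*% rbind(hbo[p, ], hbr[p, ])      # 2 x T
      intens[2 * p - 1, ] <- baseline * exp(-dod[1, ])
      intens[2 * p, ] <- baseline * exp(-dod[2, ])
    }
    structure(list(intensities = intens, channels = channels, fs = fs,
                   age = age, distance_cm = distance_cm, baseline = baseline,
                   duration = T_ / fs, truth_hbo = hbo, truth_hbr = hbr,
                   spike_idx = spike_idx, shift_idx = shift_idx),
              class = "tpdc_recording")
  })
}

#' @export
print.tpdc_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording: %d source-detector pairs x 2 wavelengths, %d samples at %.4g Hz (%.1f s), age %.1f y\n",
              nrow(x$intensities) / 2, ncol(x$intensities), x$fs, x$duration, x$age))
  invisible(x)
}
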