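#' Default whole-head montage
#'
#' A 122-channel continuous-wave montage (one channel per source-detector
#' pair; each pair is measured at both 760 and 850 nm). Channel ids are
#' 1..122 with synthetic source/detector indices laid out row-wise.
#'
#' @return Data frame with columns `channel`, `source`, `detector`.
#' @export
default_montage <- function() {
  n <- 122L
  data.frame(channel = seq_len(n),
             source = ((seq_len(n) - 1L) %/% 4L) + 1L,
             detector = ((seq_len(n) - 1L) %% 4L) + 1L + ((seq_len(n) - 1L) %/% 4L))
}

#' Default channel-to-ROI map
#'
#' Of the 122 montage channels, 40 cover the reading network and are pooled
#' into the 7 regions of interest with per-ROI channel counts
#' 8 (IFG), 6 (STG), 8 (MTG), 6 (FFG), 4 (SMG), 4 (IPL), 4 (ANG),
#' split evenly between the left and right probes.
#'
#' @return Data frame with columns `channel`, `roi`, `hemisphere`.
#' @export
default_roi_map <- function() {
  counts <- c(IFG = 8L, STG = 6L, MTG = 8L, FFG = 6L, SMG = 4L, IPL = 4L, ANG = 4L)
  roi <- rep(names(counts), counts)
  hemi <- unlist(lapply(counts, function(k) rep(c("left", "right"), each = k / 2L)),
                 use.names = FALSE)
  # mapped channels are interleaved through the montage, as on a real cap
  data.frame(channel = seq(3L, by = 3L, length.out = sum(counts)),
             roi = roi, hemisphere = hemi, stringsAsFactors = FALSE)
}

# internal: validate a roi map against a set of available channels
validate_roi_map <- function(roi_map, channels) {
  need <- c("channel", "roi", "hemisphere")
  if (!all(need %in% names(roi_map)))
    stop_tpdc("tpdc_mapping_error", "roi map must have columns %s", paste(need, collapse = ", "))
  missing <- setdiff(roi_map$channel, channels)
  if (length(missing))
    stop_tpdc("tpdc_mapping_error", "roi map refers to unknown channel(s) %s",
              paste(missing, collapse = ", "))
  for (h in unique(roi_map$hemisphere)) {
    rois <- unique(roi_map$roi[roi_map$hemisphere == h])
    empty <- setdiff(roi_labels(), rois)
    if (length(empty))
      stop_tpdc("tpdc_mapping_error", "ROI(s) %s have no mapped channel in %s hemisphere",
                paste(empty, collapse = ", "), h)
  }
  invisible(roi_map)
}
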