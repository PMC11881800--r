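#' Write a recording to long-format CSV
#'
#' Columns `time`, `channel`, `source`, `detector`, `wavelength`,
#' `intensity`; acquisition metadata (fs, age, distance, baseline) goes into
#' a JSON sidecar manifest `<path>.json`.
#'
#' @param recording A `tpdc_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "tpdc_recording"))
  ch <- recording$channels
  T_ <- ncol(recording$intensities)
  tgrid <- (seq_len(T_) - 1) / recording$fs
  df <- data.frame(time = rep(tgrid, each = nrow(ch)),
                   channel = rep(ch$channel, T_),
                   source = rep(ch$source, T_),
                   detector = rep(ch$detector, T_),
                   wavelength = rep(ch$wavelength, T_),
                   intensity = as.vector(recording$intensities))
  utils::write.csv(df, path, row.names = FALSE)
  write_manifest(paste0(path, ".json"),
                 list(format = "long_csv", fs = recording$fs,
                      age = recording$age, distance_cm = recording$distance_cm,
                      baseline = recording$baseline,
                      n_channels = nrow(ch), n_samples = T_))
  invisible(path)
}

#' Read a recording
#'
#' Reads a long-format CSV written by [write_recording()] (or any file with
#' columns `time`, `source`, `detector`, `wavelength`, `intensity`),
#' validates that every source-detector pair carries both wavelengths, and
#' restores metadata from the sidecar manifest when present (otherwise the
#' sampling rate is inferred from the time column).
#'
#' @param path Input path.
#' @param format `"csv"`; `"snirf"` is recognised but not supported in this
#'   build (no HDF5 reader dependency).
#' @return A `tpdc_recording`.
#' @export
read_recording <- function(path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf")
    stop_tpdc("tpdc_format_error",
              "SNIRF input is not supported by this build; export to long-format CSV")
  if (!file.exists(path)) stop_tpdc("tpdc_io_error", "file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("time", "source", "detector", "wavelength", "intensity")
  if (!all(need %in% names(df)))
    stop_tpdc("tpdc_parse_error", "missing column(s): %s",
              paste(setdiff(need, names(df)), collapse = ", "))
  if (!"channel" %in% names(df))
    df$channel <- match(paste(df$source, df$detector),
                        unique(paste(df$source, df$detector)))
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  times <- sort(unique(df$time))
  fs <- meta$fs %||% (1 / stats::median(diff(times)))
  keys <- unique(df[, c("channel", "source", "detector", "wavelength")])
  keys <- keys[order(keys$channel, keys$wavelength), ]
  for (pid in unique(keys$channel)) {
    wl <- keys$wavelength[keys$channel == pid]
    if (length(wl) != 2 || length(unique(wl)) != 2)
      stop_tpdc("tpdc_schema_error",
                "source-detector pair (channel %s) lacks a two-wavelength partner", pid)
  }
  intens <- matrix(NA_real_, nrow(keys), length(times))
  ti <- match(df$time, times)
  ri <- match(paste(df$channel, df$wavelength),
              paste(keys$channel, keys$wavelength))
  intens[cbind(ri, ti)] <- df$intensity
  if (anyNA(intens))
    stop_tpdc("tpdc_parse_error", "incomplete channel x time grid in %s", path)
  channels <- data.frame(row = seq_len(nrow(keys)), keys, row.names = NULL)
  structure(list(intensities = intens, channels = channels, fs = fs,
                 age = meta$age %||% NA_real_,
                 distance_cm = meta$distance_cm %||% 3,
                 baseline = meta$baseline %||% NA_real_,
                 duration = length(times) / fs),
            class = "tpdc_recording")
}

#' Write a ground-truth network as JSON
#' @param network A `tpdc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "tpdc_network"))
  jsonlite::write_json(list(n_rois = network$n_rois, model_order = network$model_order,
                            self_coef = network$self_coef, edges = network$edges),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth network from JSON
#' @param path Input path.
#' @return A `tpdc_network`.
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(x$edges)
  if (!nrow(edges))
    edges <- data.frame(source = integer(0), target = integer(0),
                        coupling = numeric(0), lag = integer(0),
                        tv_profile = character(0))
  structure(list(n_rois = as.integer(x$n_rois), edges = edges,
                 model_order = as.integer(x$model_order),
                 self_coef = x$self_coef),
            class = "tpdc_network")
}

#' Write cohort tables to CSV
#'
#' Writes `clinical.csv`, `reading.csv` and `connections.csv` (subjects in
#' rows) plus a JSON manifest into a directory.
#'
#' @param cohort A `tpdc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tpdc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$reading, file.path(dir, "reading.csv"), row.names = FALSE)
  conn <- data.frame(subject = rownames(cohort$connections),
                     cohort$connections, check.names = FALSE)
  utils::write.csv(conn, file.path(dir, "connections.csv"), row.names = FALSE)
  write_manifest(file.path(dir, "cohort_manifest.json"),
                 list(n_ci = sum(cohort$clinical$group == "CI"),
                      n_th = sum(cohort$clinical$group == "TH"),
                      n_connections = ncol(cohort$connections)))
  invisible(dir)
}

#' Write a significance table as TSV
#' @param sig A `tpdc_significance`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_significance <- function(sig, path) {
  stopifnot(inherits(sig, "tpdc_significance"))
  utils::write.table(sig$table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(paste0(path, ".json"),
                 list(n_iterations = sig$config$n_iterations,
                      n_windows = sig$config$n_windows,
                      percentile = sig$config$percentile,
                      seed = sig$config$seed))
  invisible(path)
}
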