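#' @keywords internal
"_PACKAGE"

# internal: NULL-coalescing
`%||%` <- function(x, y) if (is.null(x)) y else x

# internal: scoped RNG; every stochastic operation takes an explicit seed and
# restores the caller's RNG state on exit
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# internal: derive a child seed from a base seed and a stage label, kept
# within the 32-bit integer range
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_tpdc <- function(class, msg, ...) {
  stop(structure(class = c(class, "tpdc_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Canonical ROI labels of the reading network
#'
#' The seven bilateral reading-related regions used throughout the package:
#' inferior frontal gyrus (IFG), superior temporal gyrus (STG), middle
#' temporal gyrus (MTG), fusiform gyrus (FFG), supramarginal gyrus (SMG),
#' inferior parietal lobule (IPL) and angular gyrus (ANG).
#'
#' @return Character vector of length 7.
#' @export
roi_labels <- function() c("IFG", "STG", "MTG", "FFG", "SMG", "IPL", "ANG")

# internal: enumerate the 42 ordered off-diagonal (source, target) pairs
connection_pairs <- function(labels = roi_labels()) {
  g <- expand.grid(target = labels, source = labels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[g$target != g$source, c("source", "target")]
  rownames(g) <- NULL
  g
}

# internal: write a JSON sidecar manifest next to an output file
write_manifest <- function(path, params) {
  params$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  params$package_version <- as.character(utils::packageVersion("tpdc"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
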