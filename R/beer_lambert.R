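#' Age-dependent differential path length factor
#'
#' DPF scales the source-detector separation into an effective optical path
#' length. The package uses the paediatric age model
#' \deqn{DPF(a) = 4.99 + 0.067 \, a^{0.814}}
#' with age \eqn{a} in years, so that \code{dpf(0) == 4.99}.
#'
#' @param age_years Age in years, `>= 0`.
#' @return Dimensionless DPF value (vectorised over `age_years`).
#' @examples
#' dpf(0)   # 4.99
#' dpf(1)   # 5.057
#' @export
dpf <- function(age_years) {
  if (any(age_years < 0)) stop_tpdc("tpdc_parameter_error", "age must be >= 0")
  4.99 + 0.067 * age_years^0.814
}

#' Extinction coefficient table for 760/850 nm
#'
#' Molar extinction coefficients of oxy- (HbO) and deoxyhaemoglobin (HbR) at
#' the two measurement wavelengths, from the Gratzer/Prahl compilation,
#' shipped as a versioned CSV. Units: 1/(cm M).
#'
#' @param path Optional path to an alternative table with columns
#'   `wavelength_nm`, `e_hbo`, `e_hbr`.
#' @return Data frame with one row per wavelength.
#' @export
extinction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "extinction_760_850.csv", package = "tpdc")
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "e_hbo", "e_hbr")
  if (!all(need %in% names(tab)))
    stop_tpdc("tpdc_configuration_error", "extinction table must have columns %s",
              paste(need, collapse = ", "))
  tab
}

# internal: 2x2 extinction matrix (rows: wavelengths, cols: HbO, HbR) for a
# wavelength pair, in 1/(cm * microM) so concentrations come out in microM
extinction_matrix <- function(wavelengths, table = extinction_table()) {
  idx <- match(wavelengths, table$wavelength_nm)
  if (anyNA(idx))
    stop_tpdc("tpdc_configuration_error", "no extinction data for wavelength(s) %s",
              paste(wavelengths[is.na(idx)], collapse = ", "))
  E <- as.matrix(table[idx, c("e_hbo", "e_hbr")]) * 1e-6
  dimnames(E) <- list(as.character(wavelengths), c("hbo", "hbr"))
  if (abs(det(E)) < 1e-12)
    stop_tpdc("tpdc_configuration_error", "extinction matrix is singular")
  E
}
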