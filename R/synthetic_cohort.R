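#' Cohort specification for the synthetic generator
#'
#' Collects the knobs of the synthetic cohort: group sizes, the RISE score
#' scaling (mean 250, SD 15, hard range 190-310), and the planted mediation
#' structure. `mediation_effects` is a data frame with one row per planted
#' (predictor, connection, subtest) triple and columns `predictor`
#' (`"PC1"`, `"PC2"`, `"PC3"` - the latent clinical factor acting as the
#' true predictor), `connection` (label `"SRC->TGT"`), `subtest`, `a`
#' (predictor to connectivity path, connectivity units per factor SD) and `b`
#' (connectivity to reading path, RISE points per connectivity unit).
#'
#' @param n_ci,n_th Group sizes (defaults 50 cochlear-implant, 25 typical
#'   hearing).
#' @param mediation_effects Planted paths; `NULL` for the default planting,
#'   a zero-row data frame for a null cohort.
#' @param score_mean,score_sd,score_min,score_max RISE scale parameters.
#' @param seed Integer seed.
#' @return Object of class `tpdc_cohort_spec`.
#' @export
cohort_spec <- function(n_ci = 50, n_th = 25, mediation_effects = NULL,
                        score_mean = 250, score_sd = 15,
                        score_min = 190, score_max = 310, seed = 0) {
  if (n_ci <= 0 || n_th <= 0)
    stop_tpdc("tpdc_parameter_error", "group sizes must be positive")
  if (!(score_min < score_mean && score_mean < score_max))
    stop_tpdc("tpdc_parameter_error", "need score_min < score_mean < score_max")
  if (is.null(mediation_effects)) mediation_effects <- default_mediation_effects()
  if (nrow(mediation_effects)) {
    need <- c("predictor", "connection", "subtest", "a", "b")
    if (!all(need %in% names(mediation_effects)))
      stop_tpdc("tpdc_specification_error",
                "mediation_effects needs columns %s", paste(need, collapse = ", "))
  }
  structure(list(n_ci = as.integer(n_ci), n_th = as.integer(n_th),
                 mediation_effects = mediation_effects, score_mean = score_mean,
                 score_sd = score_sd, score_min = score_min,
                 score_max = score_max, seed = seed),
            class = "tpdc_cohort_spec")
}

#' RISE subtest names
#' @return Character vector of the six subtests.
#' @export
subtest_labels <- function() c("WRDC", "VOC", "MORPH", "SEN", "EFFIC", "RCOMP")

# default planting: a primary-intervention factor effect on four early
# reading connections; magnitudes are calibration choices (see vignette)
default_mediation_effects <- function() {
  data.frame(predictor = "PC1",
             connection = c("STG->IFG", "MTG->IFG", "FFG->MTG", "STG->MTG"),
             subtest = c("WRDC", "VOC", "MORPH", "SEN"),
             a = -0.5, b = 6, stringsAsFactors = FALSE)
}

#' Generate a synthetic clinical cohort
#'
#' Produces the three tables the cohort-level analysis consumes: a clinical
#' table (10 intervention/development variables for the CI group, drawn with
#' block covariance so that PCA recovers a primary-intervention, a
#' secondary-intervention and a development component), a reading table (six
#' RISE subtests scaled to mean 250 / SD 15 and clamped to the 190-310
#' scale), and per-subject strengths for the 42 directed reading-network
#' connections. Mediation structure is planted as
#' `M = mu + a X + noise` and `Y = 250 + offset + b M + noise`, where the
#' reading noise variance is topped up so each subtest's total SD equals
#' `score_sd`; infeasibly large paths therefore raise a specification error.
#' Typical-hearing subjects get connection strengths with a higher baseline
#' and reading scores with a positive age slope.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `tpdc_cohort`: list with `clinical`, `reading`
#'   (data frames keyed by `subject`), `connections` (subject x 42 matrix,
#'   columns `"SRC->TGT"`), and `truth` (planted paths and latent factors).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_ci = 30, n_th = 15, seed = 1))
#' colMeans(coh$reading[, subtest_labels()])
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "tpdc_cohort_spec"))
    stop_tpdc("tpdc_parameter_error", "spec must be a tpdc_cohort_spec")
  n_ci <- spec$n_ci; n_th <- spec$n_th; n <- n_ci + n_th
  pairs <- connection_pairs()
  conn_labels <- paste0(pairs$source, "->", pairs$target)
  eff <- spec$mediation_effects
  if (nrow(eff)) {
    bad <- setdiff(eff$connection, conn_labels)
    if (length(bad))
      stop_tpdc("tpdc_specification_error", "unknown connection(s) %s",
                paste(bad, collapse = ", "))
    bad <- setdiff(eff$subtest, subtest_labels())
    if (length(bad))
      stop_tpdc("tpdc_specification_error", "unknown subtest(s) %s",
                paste(bad, collapse = ", "))
  }

  with_seed(spec$seed, {
    ## --- clinical table, CI group: three latent blocks ------------------
    r <- 0.8  # within-block factor loading (squared correlation ~ 0.8)
    F1 <- stats::rnorm(n_ci); F2 <- stats::rnorm(n_ci); F3 <- stats::rnorm(n_ci)
    mix <- function(f) sqrt(r) * f + sqrt(1 - r) * stats::rnorm(n_ci)
    age_first_ci <- pmax(1.9832 + 0.9751 * mix(F1), 0.25)
    age_first_ha <- pmax(1.0006 + 0.8507 * mix(F1), 0.08)
    dur_deaf_first_ci <- pmax(0.9 * age_first_ci + 0.15 * stats::rnorm(n_ci), 0)
    dur_deaf_left_ci <- dur_deaf_first_ci + 0.3 * abs(stats::rnorm(n_ci))
    age_bilateral_ci <- pmax(3.4152 + 2.568 * mix(F2), age_first_ci + 0.1)
    # derived chart entries carry ~2-week reporting jitter, so the clinical
    # table is full rank (no exact linear identities)
    time_between_bilateral <- pmax(age_bilateral_ci - age_first_ci +
                                     0.05 * stats::rnorm(n_ci), 0.05)
    dur_deaf_right_ci <- pmax(0.9 * age_bilateral_ci + 0.3 * abs(stats::rnorm(n_ci)), 0)
    age_at_testing_ci <- pmin(pmax(12.22 + 2.9017 * mix(F3), 7), 17)
    head_size_ci <- 53 + 2.2 * mix(F3)
    # hearing age = chronological age minus age at first hearing
    # intervention, whichever device came first (with reporting jitter)
    hearing_age_ci <- age_at_testing_ci - pmin(age_first_ha, age_first_ci) +
      0.05 * stats::rnorm(n_ci)

    age_at_testing_th <- pmin(pmax(12.08 + 3.1081 * stats::rnorm(n_th), 7), 17)
    clinical <- data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      group = rep(c("CI", "TH"), c(n_ci, n_th)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age_first_ci = c(age_first_ci, rep(NA, n_th)),
      age_first_ha = c(age_first_ha, rep(NA, n_th)),
      dur_deaf_first_ci = c(dur_deaf_first_ci, rep(NA, n_th)),
      dur_deaf_left_ci = c(dur_deaf_left_ci, rep(NA, n_th)),
      dur_deaf_right_ci = c(dur_deaf_right_ci, rep(NA, n_th)),
      time_between_bilateral = c(time_between_bilateral, rep(NA, n_th)),
      age_bilateral_ci = c(age_bilateral_ci, rep(NA, n_th)),
      age_at_testing = c(age_at_testing_ci, age_at_testing_th),
      head_size = c(head_size_ci, 53 + 2.2 * stats::rnorm(n_th)),
      hearing_age = c(hearing_age_ci, age_at_testing_th),
      stringsAsFactors = FALSE)

    ## --- connection strengths -------------------------------------------
    factors <- cbind(PC1 = F1, PC2 = F2, PC3 = F3)
    mu_c <- stats::runif(42, 0.2, 0.5)
    sigma_m <- 0.15
    M_ci <- matrix(rep(mu_c, each = n_ci), n_ci, 42) +
      sigma_m * matrix(stats::rnorm(n_ci * 42), n_ci, 42)
    if (nrow(eff)) {
      aggr <- stats::aggregate(a ~ predictor + connection, data = eff,
                               FUN = function(z) z[1])
      for (i in seq_len(nrow(aggr))) {
        ci <- match(aggr$connection[i], conn_labels)
        M_ci[, ci] <- M_ci[, ci] + aggr$a[i] * factors[, aggr$predictor[i]]
      }
    }
    # TH: same architecture, higher baseline, no clinical-factor dependence
    M_th <- matrix(rep(mu_c + 0.15, each = n_th), n_th, 42) +
      sigma_m * matrix(stats::rnorm(n_th * 42), n_th, 42)
    connections <- rbind(M_ci, M_th)
    colnames(connections) <- conn_labels
    rownames(connections) <- clinical$subject

    ## --- reading scores --------------------------------------------------
    # CI/TH offsets balance to a grand mean of score_mean at the default
    # 2:1 group ratio
    ci_offset <- -spec$score_sd / 6; th_offset <- spec$score_sd / 3
    th_age_slope <- 2.5  # RISE points per year, TH development effect
    reading <- data.frame(subject = clinical$subject, group = clinical$group,
                          stringsAsFactors = FALSE)
    for (s in subtest_labels()) {
      sys_ci <- rep(0, n_ci); var_sys <- 0
      rows <- if (nrow(eff)) which(eff$subtest == s) else integer(0)
      for (i in rows) {
        ci <- match(eff$connection[i], conn_labels)
        sys_ci <- sys_ci + eff$b[i] * M_ci[, ci]
      }
      if (length(rows)) var_sys <- stats::var(sys_ci) else var_sys <- 0
      resid_var <- spec$score_sd^2 - var_sys
      if (resid_var <= 0)
        stop_tpdc("tpdc_specification_error",
                  "planted paths for %s imply negative residual variance", s)
      y_ci <- spec$score_mean + ci_offset + (sys_ci - mean(sys_ci)) +
        sqrt(resid_var) * stats::rnorm(n_ci)
      resid_var_th <- spec$score_sd^2 - th_age_slope^2 * stats::var(age_at_testing_th)
      y_th <- spec$score_mean + th_offset +
        th_age_slope * (age_at_testing_th - mean(age_at_testing_th)) +
        sqrt(max(resid_var_th, 1)) * stats::rnorm(n_th)
      reading[[s]] <- pmin(pmax(c(y_ci, y_th), spec$score_min), spec$score_max)
    }

    structure(list(clinical = clinical, reading = reading,
                   connections = connections,
                   truth = list(mediation_effects = eff, mu = mu_c,
                                factors = factors, sigma_m = sigma_m)),
              class = "tpdc_cohort")
  })
}

#' @export
print.tpdc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d CI + %d TH subjects, %d connections, %d planted mediation paths\n",
              sum(x$clinical$group == "CI"), sum(x$clinical$group == "TH"),
              ncol(x$connections), nrow(x$truth$mediation_effects)))
  invisible(x)
}
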