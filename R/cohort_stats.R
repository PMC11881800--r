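#' Clinical variable names used by the PCA
#' @return Character vector of the 10 clinical measures.
#' @export
clinical_variables <- function() {
  c("age_first_ci", "age_first_ha", "dur_deaf_first_ci", "dur_deaf_left_ci",
    "dur_deaf_right_ci", "time_between_bilateral", "age_bilateral_ci",
    "age_at_testing", "head_size", "hearing_age")
}

#' Principal component analysis of the clinical measures
#'
#' Standardizes the 10 clinical intervention/development variables of the
#' CI group, eigen-decomposes their correlation matrix, retains components
#' with eigenvalue `> 1`, and applies an oblique promax rotation (the
#' convention behind a reported pattern matrix). Subject scores for the
#' rotated components are computed by the regression method and are the
#' predictors of the mediation battery.
#'
#' @param clinical Clinical table (see [generate_cohort()]); rows with
#'   `group != "CI"` are dropped.
#' @param rotation `"promax"` (default), `"varimax"` or `"none"`.
#' @param variables Variables entering the PCA.
#' @return Object of class `tpdc_pca`: `loadings` (pattern matrix,
#'   variable x component), `scores` (subject x component),
#'   `scores_unrotated`, `eigenvalues`, `variance_explained` (%),
#'   `n_retained`, `rotation`.
#' @export
run_pca <- function(clinical, rotation = c("promax", "varimax", "none"),
                    variables = clinical_variables()) {
  rotation <- match.arg(rotation)
  dat <- clinical
  if ("group" %in% names(dat)) dat <- dat[dat$group == "CI", , drop = FALSE]
  miss <- setdiff(variables, names(dat))
  if (length(miss))
    stop_tpdc("tpdc_parameter_error", "missing clinical variable(s) %s",
              paste(miss, collapse = ", "))
  X <- as.matrix(dat[, variables])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= ncol(X) + 1)
    stop_tpdc("tpdc_parameter_error", "need more subjects than variables")
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping constant variable(s): ",
            paste(variables[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  Z <- scale(X)
  R <- stats::cor(X)
  if (anyNA(R)) stop_tpdc("tpdc_rank_error", "correlation matrix is undefined")
  e <- eigen(R, symmetric = TRUE)
  eigval <- e$values
  k <- max(1L, sum(eigval > 1))
  L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(eigval[seq_len(k)]), k)
  rownames(L) <- colnames(X)
  scores_un <- Z %*% e$vectors[, seq_len(k), drop = FALSE]
  if (rotation == "none" || k == 1) {
    pattern <- L
  } else if (rotation == "varimax") {
    pattern <- stats::varimax(L)$loadings[]
  } else {
    pattern <- stats::promax(L, m = 4)$loadings[]
  }
  colnames(pattern) <- paste0("PC", seq_len(k))
  # regression-method factor scores for the (possibly oblique) pattern;
  # eigen-truncated pseudoinverse so rank-deficient tables (collinear
  # clinical variables) still score
  tol <- 1e-10 * max(eigval)
  keep_e <- eigval > tol
  Rinv <- e$vectors[, keep_e, drop = FALSE] %*%
    diag(1 / eigval[keep_e], sum(keep_e)) %*% t(e$vectors[, keep_e, drop = FALSE])
  scores <- Z %*% (Rinv %*% pattern)
  colnames(scores) <- colnames(pattern)
  colnames(scores_un) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(scores_un) <-
    if ("subject" %in% names(dat)) dat$subject[stats::complete.cases(dat[, variables])]
    else NULL
  structure(list(loadings = pattern, scores = scores,
                 scores_unrotated = scores_un, eigenvalues = eigval,
                 variance_explained = 100 * eigval / sum(eigval),
                 n_retained = k, rotation = rotation,
                 n_subjects = nrow(X)),
            class = "tpdc_pca")
}

#' @export
print.tpdc_pca <- function(x, ...) {
  cat(sprintf("Clinical PCA (%s rotation): %d components retained (eigenvalue > 1) from %d subjects\n",
              x$rotation, x$n_retained, x$n_subjects))
  cat(sprintf("Variance explained: %s\n",
              paste(sprintf("%.1f%%", x$variance_explained[seq_len(x$n_retained)]),
                    collapse = ", ")))
  cat("Pattern matrix:\n")
  print(round(x$loadings, 2))
  invisible(x)
}

# internal: closed-form paths of the saturated linear mediation model
mediation_paths <- function(x, m, y) {
  sxx <- stats::var(x); sxm <- stats::cov(x, m); smm <- stats::var(m)
  sxy <- stats::cov(x, y); smy <- stats::cov(m, y)
  a <- sxm / sxx
  det <- sxx * smm - sxm^2
  b <- (sxx * smy - sxm * sxy) / det
  cprime <- (smm * sxy - sxm * smy) / det
  total <- sxy / sxx
  c(a = a, b = b, cprime = cprime, total = total, indirect = a * b)
}

#' Fit a single-mediator linear mediation model
#'
#' Saturated linear path model `m = a x + e1`, `y = b m + c' x + e2`,
#' estimated by least squares (equal to maximum likelihood here), with a
#' percentile bootstrap over subjects for the indirect effect `a * b`.
#' The algebraic identity `total = direct + indirect` holds exactly.
#'
#' @param x Predictor scores (e.g. a clinical principal component).
#' @param m Mediator (a connection strength).
#' @param y Outcome (a reading subtest score).
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @param conf_level CI coverage (default 0.95).
#' @return Object of class `tpdc_mediation`: paths `a`, `b`, `cprime`,
#'   `total`, `indirect`, bootstrap `ci`, two-sided `p_value`, `n`.
#' @export
fit_mediation <- function(x, m, y, n_boot = 5000, seed = 0, conf_level = 0.95) {
  cc <- stats::complete.cases(x, m, y)
  x <- x[cc]; m <- m[cc]; y <- y[cc]
  n <- length(x)
  if (n < 10) stop_tpdc("tpdc_parameter_error", "need at least 10 complete cases")
  if (stats::var(m) == 0)
    stop_tpdc("tpdc_degenerate_error", "mediator has zero variance")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_tpdc("tpdc_degenerate_error", "predictor/outcome has zero variance")
  est <- mediation_paths(x, m, y)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    boot_indirect(x, m, y, idx)
  })
  alpha <- 1 - conf_level
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p <- 2 * min((sum(boot <= 0) + 1) / (n_boot + 1),
               (sum(boot >= 0) + 1) / (n_boot + 1))
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 cprime = unname(est["cprime"]), total = unname(est["total"]),
                 indirect = unname(est["indirect"]), ci = ci,
                 p_value = min(p, 1), n = n, n_boot = n_boot,
                 boot = boot),
            class = "tpdc_mediation")
}

# internal: vectorized bootstrap of the indirect effect over an index matrix
boot_indirect <- function(x, m, y, idx) {
  n <- nrow(idx)
  X <- matrix(x[idx], n); M <- matrix(m[idx], n); Y <- matrix(y[idx], n)
  mx <- colMeans(X); mm <- colMeans(M); my <- colMeans(Y)
  sxx <- colMeans(X * X) - mx^2
  sxm <- colMeans(X * M) - mx * mm
  smm <- colMeans(M * M) - mm^2
  sxy <- colMeans(X * Y) - mx * my
  smy <- colMeans(M * Y) - mm * my
  a <- sxm / sxx
  b <- (sxx * smy - sxm * sxy) / (sxx * smm - sxm^2)
  a * b
}

#' @export
print.tpdc_mediation <- function(x, ...) {
  cat(sprintf("Linear mediation (n = %d): a = %.3f, b = %.3f, c' = %.3f\n",
              x$n, x$a, x$b, x$cprime))
  cat(sprintf("indirect a*b = %.3f [%.3f, %.3f], p = %.4f (%d bootstrap resamples)\n",
              x$indirect, x$ci[1], x$ci[2], x$p_value, x$n_boot))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_tpdc("tpdc_domain_error", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full mediation battery
#'
#' One mediation model per (retained component) x (42 connections) x
#' (6 subtests), with Benjamini-Hochberg correction applied within each
#' component's family of 252 tests.
#'
#' @param pca A `tpdc_pca` (or a subject x component score matrix).
#' @param connections Subject x connection matrix (42 columns named
#'   `"SRC->TGT"`); rows must align with the PCA scores' subjects.
#' @param reading Reading table with the six subtest columns, aligned the
#'   same way (a `subject` column is used for the join when present).
#' @param n_boot Bootstrap resamples per model (default 500; raise for
#'   final inference).
#' @param seed Integer seed.
#' @param alpha BH significance level for the reported `significant` flag.
#' @return Data frame with one row per test: `predictor`, `connection`,
#'   `subtest`, `a`, `b`, `indirect`, `p_raw`, `p_bh`, `significant`.
#' @export
run_mediation_battery <- function(pca, connections, reading, n_boot = 500,
                                  seed = 0, alpha = 0.05) {
  scores <- if (inherits(pca, "tpdc_pca")) pca$scores else as.matrix(pca)
  connections <- as.matrix(connections)
  subtests <- intersect(subtest_labels(), names(reading))
  if (!length(subtests))
    stop_tpdc("tpdc_parameter_error", "reading table has no RISE subtest columns")
  ids <- rownames(scores)
  if (!is.null(ids) && "subject" %in% names(reading)) {
    ord <- match(ids, reading$subject)
    if (anyNA(ord)) stop_tpdc("tpdc_join_error", "subject ids do not align")
    reading <- reading[ord, , drop = FALSE]
    if (!is.null(rownames(connections))) {
      ordc <- match(ids, rownames(connections))
      if (anyNA(ordc)) stop_tpdc("tpdc_join_error", "subject ids do not align")
      connections <- connections[ordc, , drop = FALSE]
    }
  }
  if (nrow(connections) != nrow(scores) ||
      nrow(reading) != nrow(scores))
    stop_tpdc("tpdc_join_error", "tables have differing numbers of subjects")
  n <- nrow(scores)
  out <- list()
  for (pc in colnames(scores)) {
    x <- scores[, pc]
    idx <- with_seed(derive_seed(seed, pc),
                     matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot))
    rows <- expand.grid(connection = colnames(connections), subtest = subtests,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    res <- matrix(NA_real_, nrow(rows), 4,
                  dimnames = list(NULL, c("a", "b", "indirect", "p_raw")))
    for (r in seq_len(nrow(rows))) {
      m <- connections[, rows$connection[r]]
      y <- reading[[rows$subtest[r]]]
      est <- mediation_paths(x, m, y)
      boot <- boot_indirect(x, m, y, idx)
      p <- 2 * min((sum(boot <= 0) + 1) / (n_boot + 1),
                   (sum(boot >= 0) + 1) / (n_boot + 1))
      res[r, ] <- c(est["a"], est["b"], est["indirect"], min(p, 1))
    }
    tab <- cbind(data.frame(predictor = pc, stringsAsFactors = FALSE),
                 rows, as.data.frame(res))
    tab$p_bh <- bh_adjust(tab$p_raw)
    tab$significant <- tab$p_bh < alpha
    out[[pc]] <- tab
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group comparisons of reading scores
#'
#' Per subtest: Welch's t-test (Satterthwaite degrees of freedom) for the
#' means and the Mann-Whitney U-test for the distributions.
#'
#' @param reading Reading table with a `group` column and subtest columns.
#' @param group_col Name of the group column (default `"group"`).
#' @param subtests Subtests to compare.
#' @return Data frame: `subtest`, `t`, `df`, `p_welch`, `U`, `p_mw`,
#'   `mean_1`, `mean_2` (groups in sorted label order).
#' @export
compare_groups <- function(reading, group_col = "group",
                           subtests = intersect(subtest_labels(), names(reading))) {
  g <- factor(reading[[group_col]])
  if (nlevels(g) != 2)
    stop_tpdc("tpdc_parameter_error", "need exactly two groups")
  if (any(table(g) < 2))
    stop_tpdc("tpdc_sample_size_error", "each group needs at least 2 subjects")
  lv <- levels(g)
  do.call(rbind, lapply(subtests, function(s) {
    x <- reading[[s]][g == lv[1]]
    y <- reading[[s]][g == lv[2]]
    tt <- stats::t.test(x, y, var.equal = FALSE)
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    data.frame(subtest = s, t = unname(tt$statistic),
               df = unname(tt$parameter), p_welch = tt$p.value,
               U = unname(mw$statistic), p_mw = mw$p.value,
               mean_1 = mean(x), mean_2 = mean(y),
               stringsAsFactors = FALSE)
  }))
}

#' Reading-score regressions
#'
#' Ordinary least-squares regression of each subtest on the given
#' predictors (for the CI group, typically hearing age and age at
#' hearing-aid fit; for typical-hearing children, age alone).
#'
#' @param reading Reading table (subtest columns).
#' @param predictors Data frame of predictor columns, aligned by row.
#' @param subtests Subtests to fit.
#' @return Data frame per subtest: `r_squared`, `F`, `df1`, `df2`,
#'   `p_value`, and one slope column per predictor plus `intercept`.
#' @export
fit_reading_regression <- function(reading, predictors,
                                   subtests = intersect(subtest_labels(), names(reading))) {
  X <- as.data.frame(predictors)
  if (nrow(X) != nrow(reading))
    stop_tpdc("tpdc_join_error", "predictors and reading tables differ in length")
  Xm <- stats::model.matrix(~ ., data = X)
  if (nrow(Xm) <= ncol(Xm))
    stop_tpdc("tpdc_sample_size_error", "need n > number of predictors + 1")
  if (kappa(Xm, exact = TRUE) > 1e10)
    stop_tpdc("tpdc_collinearity_error", "predictors are collinear")
  do.call(rbind, lapply(subtests, function(s) {
    cc <- stats::complete.cases(X, reading[[s]])
    fit <- stats::lm(reading[[s]][cc] ~ ., data = X[cc, , drop = FALSE])
    sm <- summary(fit)
    fstat <- sm$fstatistic
    pv <- if (is.null(fstat)) NA_real_
          else stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    row <- data.frame(subtest = s, r_squared = sm$r.squared,
                      F = unname(fstat[1]), df1 = unname(fstat[2]),
                      df2 = unname(fstat[3]), p_value = unname(pv),
                      intercept = unname(stats::coef(fit)[1]),
                      stringsAsFactors = FALSE)
    slopes <- stats::coef(fit)[-1]
    for (nm in names(slopes)) row[[paste0("slope_", nm)]] <- unname(slopes[nm])
    row
  }))
}
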