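#' Multivariable linear model for height on one CpG's methylation
#'
#' Fits `height ~ covariates + technical PCs + methylation` by ordinary
#' least squares among patients with a non-missing height and returns the
#' methylation coefficient (cm per M-value unit) with its standard error,
#' t-statistic and two-sided p-value.
#'
#' @param height Heights in cm (may contain NA; those rows are dropped).
#' @param methylation M-values at one probe, aligned with `height`.
#' @param covariate_design Numeric design matrix of covariates including
#'   the intercept (e.g. from [build_design_matrix()] with
#'   `group_var = NULL`), aligned with `height`.
#' @param min_n Minimum number of usable observations (default 50).
#' @return List of class `height_fit`: `coefficient, se, t, p, df, n`, plus
#'   the underlying `model_fit`.
#' @export
fit_height_model <- function(height, methylation, covariate_design,
                             min_n = 50L) {
  keep <- !is.na(height)
  y <- height[keep]
  x <- methylation[keep]
  X <- cbind(covariate_design[keep, , drop = FALSE], methylation = x)
  if (length(y) < min_n)
    stop("only ", length(y), " usable observations (< ", min_n, ")")
  fit <- fit_linear_model(y, X)
  se <- fit$stdev_unscaled[["methylation"]] * sqrt(fit$sigma2)
  tstat <- fit$coefficients[["methylation"]] / se
  p <- 2 * stats::pt(-abs(tstat), df = fit$df_residual)
  structure(list(coefficient = fit$coefficients[["methylation"]],
                 se = se, t = tstat, p = p,
                 df = fit$df_residual, n = fit$n, fit = fit),
            class = "height_fit")
}

# Out-of-fold p-value for the methylation slope: the covariate-only model is
# fitted on the training folds, test heights are residualised with the
# training coefficients, and the residuals are regressed on test-fold
# methylation (simple regression with intercept). Returns slope and p per
# probe (methylation may be a matrix, probes in columns).
.fold_pvalue_residualise <- function(y_train, X_train, y_test, X_test,
                                     M_test) {
  b <- qr.coef(qr(X_train), y_train)
  r <- y_test - drop(X_test %*% b)
  m <- as.matrix(M_test)
  nt <- length(r)
  mc <- scale(m, center = TRUE, scale = FALSE)
  rc <- r - mean(r)
  sxx <- colSums(mc^2)
  slope <- colSums(mc * rc) / sxx
  rss <- sum(rc^2) - slope^2 * sxx
  df <- nt - 2L
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(slope = slope, p = p)
}

# Literal alternative: refit the full model (covariates + methylation)
# within the test fold alone, one probe at a time.
.fold_pvalue_refit <- function(y_test, X_test, M_test) {
  m <- as.matrix(M_test)
  np <- ncol(m)
  slope <- p <- numeric(np)
  for (j in seq_len(np)) {
    hf <- fit_height_model(y_test, m[, j], X_test, min_n = ncol(X_test) + 2L)
    slope[j] <- hf$coefficient
    p[j] <- hf$p
  }
  list(slope = slope, p = p)
}

#' Cross-validated Fisher-combined robustness of a methylation-height
#' association
#'
#' For each of `n_iterations` iterations the patients with a height are
#' randomly partitioned into `n_folds` folds (iteration i reseeds with
#' `seed + i`); each fold in turn serves as test fold, yielding a per-fold
#' p-value for the methylation term (see `fold_scheme`); the `n_folds`
#' p-values are combined with Fisher's method; and the iteration counts as
#' significant when the combined p-value is below `alpha`. An association is
#' deemed robust when at least 50% of iterations are significant.
#'
#' @param height Heights in cm (NA rows are dropped before partitioning).
#' @param methylation M-value matrix (samples x probes) aligned with
#'   `height`; all probes are processed jointly, sharing fold fits.
#' @param covariate_design Covariate design matrix (with intercept),
#'   aligned with `height`.
#' @param n_folds,n_iterations,alpha Procedure parameters (defaults 10,
#'   100, 0.05).
#' @param seed Integer seed.
#' @param fold_scheme `"residualise"` (default): covariate-only model fitted
#'   on the training folds, test-fold heights residualised, p-value from the
#'   simple regression of residuals on test-fold methylation.
#'   `"refit_within_fold"`: the full model refitted inside each test fold.
#' @param robust_threshold Percentage of significant iterations required
#'   for robustness (default 50).
#' @return Data frame of class `robustness_records`, one row per probe:
#'   `probe_id, pct_significant_iterations, fisher_p_median, fisher_p_q25,
#'   fisher_p_q75, robust, mean_coefficient`.
#' @export
cv_fisher_robustness <- function(height, methylation, covariate_design,
                                 n_folds = 10L, n_iterations = 100L,
                                 alpha = 0.05, seed = 1L,
                                 fold_scheme = c("residualise",
                                                 "refit_within_fold"),
                                 robust_threshold = 50) {
  fold_scheme <- match.arg(fold_scheme)
  keep <- !is.na(height)
  y <- height[keep]
  M <- as.matrix(methylation)[keep, , drop = FALSE]
  X <- covariate_design[keep, , drop = FALSE]
  n <- length(y)
  np <- ncol(M)
  min_fold <- if (fold_scheme == "residualise") 5L else ncol(X) + 3L
  if (n < n_folds * min_fold)
    stop("too few observations (", n, ") for ", n_folds, " folds")
  probe_ids <- colnames(M)
  if (is.null(probe_ids)) probe_ids <- paste0("probe", seq_len(np))

  fisher_p <- matrix(NA_real_, n_iterations, np)
  coef_sum <- numeric(np)
  coef_n <- 0L
  for (i in seq_len(n_iterations)) {
    set.seed(seed + i)
    folds <- sample(rep(seq_len(n_folds), length.out = n))
    logp <- matrix(0, n_folds, np)
    for (f in seq_len(n_folds)) {
      te <- folds == f
      res <- if (fold_scheme == "residualise") {
        .fold_pvalue_residualise(y[!te], X[!te, , drop = FALSE],
                                 y[te], X[te, , drop = FALSE],
                                 M[te, , drop = FALSE])
      } else {
        .fold_pvalue_refit(y[te], X[te, , drop = FALSE],
                           M[te, , drop = FALSE])
      }
      logp[f, ] <- log(pmax(res$p, .Machine$double.xmin))
      coef_sum <- coef_sum + res$slope
      coef_n <- coef_n + 1L
    }
    x2 <- -2 * colSums(logp)
    fisher_p[i, ] <- stats::pchisq(x2, df = 2 * n_folds,
                                   lower.tail = FALSE)
  }
  pct <- 100 * colMeans(fisher_p < alpha)
  qs <- apply(fisher_p, 2, stats::quantile,
              probs = c(0.25, 0.5, 0.75), names = FALSE)
  structure(data.frame(
    probe_id = probe_ids,
    pct_significant_iterations = pct,
    fisher_p_median = qs[2, ],
    fisher_p_q25 = qs[1, ],
    fisher_p_q75 = qs[3, ],
    robust = pct >= robust_threshold,
    mean_coefficient = coef_sum / coef_n,
    stringsAsFactors = FALSE), class = c("robustness_records",
                                         "data.frame"))
}

#' Classify a robust association as Harm or Benefit
#'
#' `Harm` when displacing methylation in the patient-abnormal direction
#' (the sign of the patient-vs-healthy log fold change) predicts a shorter
#' height, i.e. `mean_coefficient * sign(dmp_logFC_M) < 0`; `Benefit`
#' otherwise.
#'
#' @param record One row of a `robustness_records` data frame (must be
#'   robust).
#' @param dmp_logFC_M The probe's patient-vs-healthy log fold change.
#' @return `"Harm"` or `"Benefit"`.
#' @export
classify_direction <- function(record, dmp_logFC_M) {
  if (!isTRUE(record$robust))
    stop("direction is only defined for robust associations")
  if (record$mean_coefficient * sign(dmp_logFC_M) < 0) "Harm" else "Benefit"
}

#' Add direction labels to a robustness table
#'
#' @param records A `robustness_records` data frame.
#' @param dmp_logfc Named vector of patient-vs-healthy logFC per probe.
#' @return The records with a `direction_label` column (`Harm`/`Benefit`,
#'   or `none` for non-robust rows).
#' @export
label_directions <- function(records, dmp_logfc) {
  records$direction_label <- ifelse(
    !records$robust, "none",
    ifelse(records$mean_coefficient *
             sign(dmp_logfc[records$probe_id]) < 0, "Harm", "Benefit"))
  records
}
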