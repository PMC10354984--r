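#' Fit an ordinary least-squares linear model
#'
#' Minimal least-squares fit returning the quantities needed downstream for
#' empirical-Bayes moderation: coefficients, the design-dependent unscaled
#' coefficient standard deviations `sqrt(diag((X'X)^-1))`, the residual
#' variance and its degrees of freedom.
#'
#' @param response Numeric vector (one response) or matrix with one column per
#'   response (e.g. samples x probes); rows are observations.
#' @param design Numeric design matrix, rows aligned with `response`.
#' @return An object of class `model_fit`: a list with elements
#'   `coefficients` (vector, or coefficients x responses matrix),
#'   `stdev_unscaled`, `sigma2` (residual variance(s)), `df_residual` and `n`.
#' @export
fit_linear_model <- function(response, design) {
  design <- as.matrix(design)
  y <- as.matrix(response)
  n <- nrow(design)
  if (nrow(y) != n) stop("response and design have different numbers of rows")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[seq(qrd$rank + 1L, ncol(design))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (n <= ncol(design)) stop("need more observations than design columns")
  fit <- stats::lm.fit(design, y)
  df <- n - ncol(design)
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / df
  xtxinv <- chol2inv(chol(crossprod(design)))
  su <- sqrt(diag(xtxinv))
  names(su) <- colnames(design)
  coefs <- fit$coefficients
  structure(list(
    coefficients  = if (ncol(y) == 1L) drop(coefs) else coefs,
    stdev_unscaled = su,
    sigma2        = if (ncol(y) == 1L) unname(s2) else s2,
    df_residual   = df,
    n             = n
  ), class = "model_fit")
}

#' Invert the trigamma function
#'
#' Newton iteration on `1/x`, monotone and quadratically convergent; used by
#' the method-of-moments estimator of the variance-prior degrees of freedom.
#'
#' @param y Positive numeric vector.
#' @return `x` such that `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  out <- y
  large <- y > 1e7
  small <- y < 1e-6
  out[large] <- 1 / sqrt(y[large])
  out[small] <- 1 / y[small]
  mid <- !(large | small)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits the scaled inverse-chi-square hierarchical model for residual
#' variances across probes by method of moments on the log sample variances
#' (closed-form trigamma inversion), and returns posterior (shrunken)
#' variances. When the observed dispersion of log variances is at or below
#' its sampling expectation the prior degrees of freedom are infinite and all
#' posterior variances collapse to the prior variance.
#'
#' @param s2 Vector of residual sample variances (one per probe).
#' @param df Residual degrees of freedom; scalar or vector matching `s2`.
#' @return An object of class `moderation_result`: list with `prior_df` (d0,
#'   possibly `Inf`), `prior_var` (s0^2), `posterior_var` (vector), `total_df`
#'   (df + d0) and logical `fallback` (TRUE when fewer than 2 finite
#'   variances were available and no shrinkage was applied).
#' @export
moderate_variances <- function(s2, df) {
  if (any(s2 < 0, na.rm = TRUE)) stop("variances must be non-negative")
  df <- rep_len(df, length(s2))
  if (any(df < 1, na.rm = TRUE)) stop("degrees of freedom must be >= 1")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    return(structure(list(prior_df = 0, prior_var = NA_real_,
                          posterior_var = s2, total_df = df,
                          fallback = TRUE), class = "moderation_result"))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  nk <- sum(ok)
  evar <- sum((e - emean)^2) / (nk - 1L) - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion in the log variances: complete pooling, with the
    # prior variance estimated by the plain mean (the canonical estimator)
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  structure(list(prior_df = d0, prior_var = s02, posterior_var = post,
                 total_df = df + d0, fallback = FALSE),
            class = "moderation_result")
}

#' Moderated t-test for one coefficient
#'
#' The t-statistic uses the posterior residual variance from
#' [moderate_variances()] and refers to a t distribution with `df + d0`
#' degrees of freedom; the 95% confidence interval uses the same moderated
#' standard error and degrees of freedom so that interval and p-value agree.
#'
#' @param fit A `model_fit` (vector or matrix response).
#' @param moderation A `moderation_result` aligned with the responses in `fit`.
#' @param coef_index Column index or name of the coefficient to test.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Data frame with `coefficient`, `t`, `p`, `ci_lo`, `ci_hi`,
#'   `total_df` (one row per response).
#' @export
moderated_t_test <- function(fit, moderation, coef_index, conf_level = 0.95) {
  stopifnot(inherits(fit, "model_fit"), inherits(moderation, "moderation_result"))
  cf <- fit$coefficients
  beta <- if (is.matrix(cf)) cf[coef_index, ] else cf[[coef_index]]
  su <- fit$stdev_unscaled[[coef_index]]
  post <- moderation$posterior_var
  tdf <- moderation$total_df
  se <- su * sqrt(post)
  tstat <- rep(NA_real_, length(beta))
  zero <- !is.na(se) & se == 0
  if (any(zero)) {
    warning("zero posterior variance for ", sum(zero), " response(s); p set to 0")
    tstat[zero] <- sign(beta[zero]) * Inf
  }
  tstat[!zero] <- beta[!zero] / se[!zero]
  p <- 2 * stats::pt(-abs(tstat), df = tdf)
  p[zero] <- 0
  q <- stats::qt(1 - (1 - conf_level) / 2, df = tdf)
  data.frame(coefficient = unname(beta), t = unname(tstat), p = unname(p),
             ci_lo = unname(beta - q * se), ci_hi = unname(beta + q * se),
             total_df = unname(rep_len(tdf, length(beta))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0,1\].
#' @return Adjusted q-values, in the input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Fisher's method for combining independent p-values
#'
#' Refers `-2 * sum(log(p))` to a chi-square distribution with `2k` degrees
#' of freedom.
#'
#' @param p Vector of k p-values in (0, 1].
#' @return The combined upper-tail probability.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0L) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  if (any(p == 0)) {
    warning("p-value of exactly 0 supplied; combined p is 0")
    return(0)
  }
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}
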