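#' Generate synthetic heights at 4-year follow-up
#'
#' Fills `height_4y` for patient rows of a sample sheet under
#' `height = baseline(age, sex) + sum(coef * M_probe) + covariate terms +
#' noise`, where the baseline is a smooth paediatric growth curve evaluated
#' at age at admission plus four years, methylation enters on the M-value
#' scale through `config$height_coefficients`, and a `config`-controlled
#' fraction of patients is left missing (loss to follow-up). Uses its own
#' seed stream (`config$seed + 1`), so it is deterministic given the config
#' regardless of what was generated before.
#'
#' @param sample_sheet A `sample_sheet`.
#' @param dataset The `methylation_dataset` the coefficients refer to.
#' @param config A `sim_config`.
#' @return The sample sheet with `height_4y` filled for patients (NA for
#'   healthy rows and for the missing fraction).
#' @export
generate_height <- function(sample_sheet, dataset, config) {
  stopifnot(inherits(config, "sim_config"))
  coefs <- config$height_coefficients
  if (!is.null(coefs) &&
      !all(names(coefs) %in% colnames(dataset$beta)))
    stop("height_coefficients name probes absent from the dataset")
  set.seed(config$seed + 1L)
  is_pat <- sample_sheet$group == "patient"
  np <- sum(is_pat)
  if (np == 0L) return(sample_sheet)
  age4 <- sample_sheet$age_at_admission[is_pat] + 4
  base <- 77 + 6.3 * age4 - 0.035 * age4^2 +
    1.0 * (sample_sheet$sex[is_pat] == "male") -
    0.8 * sample_sheet$syndrome[is_pat]
  meth_term <- 0
  if (!is.null(coefs) && length(coefs) > 0) {
    M <- beta_to_m(dataset$beta[sample_sheet$sample_id[is_pat],
                                names(coefs), drop = FALSE])
    meth_term <- drop(M %*% coefs)
  }
  h <- base + meth_term + stats::rnorm(np, 0, config$height_noise_sd)
  if (config$height_missing_frac > 0) {
    miss <- stats::runif(np) < config$height_missing_frac
    h[miss] <- NA_real_
  }
  sample_sheet$height_4y[is_pat] <- h
  sample_sheet
}
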