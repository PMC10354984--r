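#' Dichotomise age at exposure
#'
#' Splits age at PICU admission at the adrenarche boundary; the boundary is
#' inclusive on the older side (age 6.0 is `ge6`).
#'
#' @param age Ages in years (non-negative).
#' @param cutoff Boundary in years (default 6).
#' @return Character vector with values `lt6` / `ge6` (levels named after
#'   the default cutoff regardless of `cutoff`).
#' @export
dichotomise_age <- function(age, cutoff = 6) {
  if (any(age < 0, na.rm = TRUE)) stop("ages must be non-negative")
  ifelse(age >= cutoff, "ge6", "lt6")
}

# Age "at exposure" for interaction models: admission age for patients; for
# healthy children (never admitted) the age-matched equivalent, follow-up
# age minus the two-year follow-up interval.
.age_at_exposure <- function(sheet) {
  ifelse(sheet$group == "patient", sheet$age_at_admission,
         pmax(sheet$age_at_followup - 2, 0))
}

#' Test group-by-factor interactions at selected CpG sites
#'
#' For each probe, extends the DMP design with the factor's main effect and
#' a group-by-factor interaction term and reports the moderated p-value of
#' the interaction coefficient, uncorrected. Variances are moderated across
#' the supplied probes. Per-stratum group effects (the group coefficient
#' refitted within each factor stratum) are attached for interpretation.
#'
#' @param dataset A filtered `methylation_dataset`.
#' @param dmp_probes Probe ids to test (normally the identified DMPs).
#' @param factor One of "sex", "age_ge6".
#' @param pcs A `control_pcs` or matrix of technical covariates.
#' @param covariates Covariate columns as in the DMP design (the interaction
#'   factor itself is removed from this list automatically).
#' @param age_cutoff Cutoff for the age dichotomy (default 6).
#' @return Data frame: `probe_id, factor, interaction_p,
#'   logFC_<stratum1>, logFC_<stratum2>`.
#' @export
test_interaction <- function(dataset, dmp_probes,
                             factor = c("sex", "age_ge6"), pcs = NULL,
                             covariates = c("age_at_followup", "centre",
                                            "sex", "race_noncaucasian",
                                            "origin_noneuropean",
                                            "malignancy", "syndrome"),
                             age_cutoff = 6) {
  factor <- match.arg(factor)
  sheet <- dataset$sample_sheet
  if (factor == "age_ge6") {
    sheet$age_ge6 <- dichotomise_age(.age_at_exposure(sheet), age_cutoff)
  }
  fac <- sheet[[factor]]
  tab <- table(sheet$group, fac)
  if (any(rowSums(tab > 0) < 2L))
    stop("factor '", factor, "' is constant within group(s): ",
         paste(rownames(tab)[rowSums(tab > 0) < 2L], collapse = ", "))
  covariates <- setdiff(covariates, factor)
  design <- build_design_matrix(sheet, pcs = pcs, covariates = covariates,
                                interaction_var = factor)
  rows <- attr(design, "rows_kept")
  M <- beta_to_m(dataset$beta[rows, dmp_probes, drop = FALSE])
  fit <- fit_linear_model(M, design)
  mod <- moderate_variances(fit$sigma2, fit$df_residual)
  int_col <- grep("^group.*:", colnames(design), value = TRUE)[1]
  tt <- moderated_t_test(fit, mod, int_col)

  strata <- sort(unique(fac))
  strat_eff <- sapply(strata, function(s) {
    sub <- sheet[fac == s, , drop = FALSE]
    d <- build_design_matrix(sub, pcs = pcs, covariates = covariates)
    r <- attr(d, "rows_kept")
    idx <- match(sub$sample_id[r], rownames(dataset$beta))
    Ms <- beta_to_m(dataset$beta[idx, dmp_probes, drop = FALSE])
    f <- fit_linear_model(Ms, d)
    cf <- f$coefficients
    gcol <- grep("^group", colnames(d), value = TRUE)[1]
    if (is.matrix(cf)) cf[gcol, ] else cf[[gcol]]
  })
  out <- data.frame(probe_id = dmp_probes, factor = factor,
                    interaction_p = tt$p, stringsAsFactors = FALSE)
  strat_eff <- matrix(strat_eff, nrow = length(dmp_probes))
  colnames(strat_eff) <- paste0("logFC_", strata)
  cbind(out, strat_eff)
}

#' Glucocorticoid-treatment contrast among patients
#'
#' Among patients only, models each selected probe's M-values on
#' glucocorticoid treatment, the baseline risk factors, technical PCs, and
#' the PICU covariates (length of stay, diagnosis, severity scores,
#' randomisation arm, STRONGkids class). The GC coefficient is tested with
#' the moderated t (variances moderated across the supplied probes);
#' direction is classified against the probe's patient-vs-healthy log fold
#' change: `aggravated` when the GC shift has the same sign as the group
#' abnormality, `attenuated` otherwise.
#'
#' @param dataset A filtered `methylation_dataset`.
#' @param dmp_probes Probe ids to test.
#' @param dmp_logfc Named vector of patient-vs-healthy logFC (M units) for
#'   those probes.
#' @param pcs A `control_pcs` or matrix of technical covariates.
#' @param covariates Baseline covariates (defaults as in the DMP design).
#' @param picu_covariates Patient-only covariates added to the model.
#' @return Data frame: `probe_id, gc_logFC_M, p, direction`.
#' @export
test_gc_effect <- function(dataset, dmp_probes, dmp_logfc, pcs = NULL,
                           covariates = c("age_at_followup", "centre",
                                          "sex", "race_noncaucasian",
                                          "origin_noneuropean",
                                          "malignancy", "syndrome"),
                           picu_covariates = c("picu_los", "diagnosis",
                                               "pim3", "pelod",
                                               "randomisation_arm",
                                               "strongkids")) {
  sheet <- dataset$sample_sheet
  pat <- sheet[sheet$group == "patient", , drop = FALSE]
  if (nrow(pat) == 0L) stop("no patients in dataset")
  if (length(unique(pat$gc_treatment)) < 2L)
    stop("no variation in glucocorticoid treatment")
  pat$gc <- pat$gc_treatment
  design <- build_design_matrix(pat, pcs = pcs,
                                covariates = c("gc", covariates,
                                               picu_covariates),
                                group_var = NULL)
  rows <- attr(design, "rows_kept")
  idx <- match(pat$sample_id[rows], rownames(dataset$beta))
  M <- beta_to_m(dataset$beta[idx, dmp_probes, drop = FALSE])
  fit <- fit_linear_model(M, design)
  mod <- moderate_variances(fit$sigma2, fit$df_residual)
  tt <- moderated_t_test(fit, mod, "gc")
  ref <- dmp_logfc[dmp_probes]
  data.frame(probe_id = dmp_probes,
             gc_logFC_M = tt$coefficient, p = tt$p,
             direction = ifelse(sign(tt$coefficient) == sign(ref),
                                "aggravated", "attenuated"),
             stringsAsFactors = FALSE)
}
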