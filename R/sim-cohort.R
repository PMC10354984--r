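#' Default cohort covariate marginals
#'
#' Target marginal distributions for the synthetic two-group cohort,
#' hard-coded from the published participant characteristics but overridable:
#' patients are ~58.1% male, ~8.1% known non-Caucasian, ~17.6% known
#' non-European, ~4.8% with malignancy history, ~20.5% with a predefined
#' syndrome, ~90% medium STRONGkids risk, 210/818 glucocorticoid-treated,
#' with diagnostic categories 44.5/14.2/17.4/24.0%; healthy children are
#' ~54.1% male with near-zero malignancy/syndrome rates. Follow-up ages are
#' log-normal with the published medians and interquartile ranges.
#'
#' @return Named list of marginal parameters.
#' @export
cohort_marginals <- function() {
  list(
    male_patient = 0.581, male_healthy = 0.541,
    noncauc_patient = 0.081, noncauc_healthy = 0.082,
    noneur_patient = 0.176, noneur_healthy = 0.130,
    malig_patient = 0.048, malig_healthy = 0.0,
    syndrome_patient = 0.205, syndrome_healthy = 0.010,
    strongkids_high = 0.10,
    gc_frac = 210 / 818,
    diagnosis_probs = c(cardiac_surgery = 0.445, elective_surgery = 0.142,
                        urgent_surgery = 0.174, medical = 0.240),
    centre_probs = c(Leuven = 0.6, Rotterdam = 0.4),
    age_meanlog_patient = log(3.4), age_sdlog_patient = 0.82,
    age_meanlog_healthy = log(3.8), age_sdlog_healthy = 0.80,
    pim3_mean = -3.5, pim3_sd = 1.2,
    pelod_mean = 22, pelod_sd = 13,
    los_meanlog = log(5), los_sdlog = 0.9,
    yield_meanlog = log(500), yield_sdlog = 0.4
  )
}

#' Generate a synthetic two-group cohort sample sheet
#'
#' Draws patient and healthy-control rows with covariate marginals matching
#' [cohort_marginals()]. PICU-only fields (severity scores, randomisation
#' arm, diagnosis, glucocorticoid treatment, length of stay) are missing for
#' healthy children. Age at PICU admission is the 2-year-follow-up age minus
#' two years. `height_4y` is left missing; fill it with [generate_height()].
#' A DNA-yield column supports low-yield sample QC; `n_low_yield` randomly
#' chosen samples are given yields below any sensible threshold.
#'
#' @param n_patients,n_healthy Group sizes (>= 0).
#' @param seed Integer seed.
#' @param batch_levels Number of technical batch levels (default 8).
#' @param n_low_yield Number of samples planted with insufficient DNA yield.
#' @param marginals Marginal parameters, default [cohort_marginals()].
#' @return Data frame of class `sample_sheet`, one row per sample.
#' @export
generate_cohort <- function(n_patients, n_healthy, seed = 1L,
                            batch_levels = 8L, n_low_yield = 0L,
                            marginals = cohort_marginals()) {
  if (n_patients < 0 || n_healthy < 0) stop("counts must be >= 0")
  set.seed(seed)
  m <- marginals
  n <- n_patients + n_healthy
  group <- c(rep("patient", n_patients), rep("healthy", n_healthy))
  is_pat <- group == "patient"

  age_fu <- numeric(n)
  age_fu[is_pat] <- stats::rlnorm(n_patients, m$age_meanlog_patient,
                                  m$age_sdlog_patient)
  age_fu[!is_pat] <- stats::rlnorm(n_healthy, m$age_meanlog_healthy,
                                   m$age_sdlog_healthy)
  age_fu <- pmin(pmax(age_fu, 2.05), 19)
  age_adm <- ifelse(is_pat, pmax(age_fu - 2, 0), NA_real_)

  rb <- function(n, p) stats::runif(n) < p
  sex <- ifelse(rb(n, ifelse(is_pat, m$male_patient, m$male_healthy)),
                "male", "female")

  sheet <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    group = group,
    age_at_followup = age_fu,
    age_at_admission = age_adm,
    sex = sex,
    centre = sample(names(m$centre_probs), n, TRUE, m$centre_probs),
    race_noncaucasian = rb(n, ifelse(is_pat, m$noncauc_patient,
                                     m$noncauc_healthy)),
    origin_noneuropean = rb(n, ifelse(is_pat, m$noneur_patient,
                                      m$noneur_healthy)),
    malignancy = rb(n, ifelse(is_pat, m$malig_patient, m$malig_healthy)),
    syndrome = rb(n, ifelse(is_pat, m$syndrome_patient, m$syndrome_healthy)),
    pim3 = NA_real_, pelod = NA_real_,
    strongkids = NA_character_, randomisation_arm = NA_character_,
    diagnosis = NA_character_, gc_treatment = NA,
    picu_los = NA_real_, height_4y = NA_real_,
    batch = sample(sprintf("B%02d", seq_len(batch_levels)), n, TRUE),
    dna_yield_ng = stats::rlnorm(n, m$yield_meanlog, m$yield_sdlog),
    stringsAsFactors = FALSE)

  if (n_patients > 0) {
    sheet$pim3[is_pat] <- pmin(pmax(
      stats::rnorm(n_patients, m$pim3_mean, m$pim3_sd), -7), 1)
    sheet$pelod[is_pat] <- pmin(pmax(round(
      stats::rnorm(n_patients, m$pelod_mean, m$pelod_sd)), 0), 71)
    sheet$strongkids[is_pat] <- ifelse(rb(n_patients, m$strongkids_high),
                                       "high", "medium")
    sheet$randomisation_arm[is_pat] <- sample(c("early_PN", "late_PN"),
                                              n_patients, TRUE)
    sheet$diagnosis[is_pat] <- sample(names(m$diagnosis_probs), n_patients,
                                      TRUE, m$diagnosis_probs)
    sheet$gc_treatment[is_pat] <- rb(n_patients, m$gc_frac)
    sheet$picu_los[is_pat] <- pmax(round(
      stats::rlnorm(n_patients, m$los_meanlog, m$los_sdlog)), 1)
  }
  if (n_low_yield > 0) {
    idx <- sample(n, min(n_low_yield, n))
    sheet$dna_yield_ng[idx] <- stats::runif(length(idx), 1, 10)
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}
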