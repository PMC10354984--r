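#' Simulation configuration for synthetic methylation data
#'
#' Collects the generative parameters for [generate_methylation()] and
#' [generate_height()]. Signal M-values are drawn per probe as
#' `mu + group * delta_M + covariate effects + batch loading + noise`, then
#' transformed to beta-values via the inverse M transform
#' `beta = 2^M / (2^M + 1)`; a shared per-sample latent batch factor also
#' drives the control-probe intensities so that control-probe principal
#' components can recover it.
#'
#' @param planted_dmps Data frame with columns `probe_id`, `delta_M`
#'   (patient-minus-healthy shift on the M-value scale), or NULL.
#' @param planted_dmr List `(gene, sites, delta_M)` where `sites` are
#'   site indices within the gene (in manifest order), or NULL. For the
#'   planted member set to be exactly recoverable the run should be isolated
#'   in the manifest (flanking gaps wider than the kernel bandwidth); see
#'   [isolate_gene_run()].
#' @param batch_effect_sd Per-probe batch loading scale on the M scale.
#' @param control_batch_loading Batch loading scale on the log2
#'   control-intensity scale.
#' @param noise_sd_M Residual M-value noise standard deviation.
#' @param sex_effect_sd,age_effect_sd Standard deviations of per-probe
#'   covariate effects (M units; M units per year).
#' @param n_nonbimodal Number of samples generated without the usual bi-peak
#'   beta distribution (mid-range betas), for sample-QC testing.
#' @param n_failed_probes Number of signal probes generated with high
#'   detection p-values in all samples, for probe-QC testing.
#' @param height_coefficients Named numeric vector: cm of height at 4-year
#'   follow-up per M-value unit, per probe.
#' @param height_noise_sd Height residual SD in cm.
#' @param height_missing_frac Fraction of patients without a 4-year height
#'   (default 160/818, the published attrition).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(planted_dmps = NULL, planted_dmr = NULL,
                       batch_effect_sd = 0.3, control_batch_loading = 1.0,
                       noise_sd_M = 0.5, sex_effect_sd = 0.05,
                       age_effect_sd = 0.01,
                       n_nonbimodal = 0L, n_failed_probes = 0L,
                       height_coefficients = NULL, height_noise_sd = 5,
                       height_missing_frac = 160 / 818, seed = 1L) {
  stopifnot(batch_effect_sd >= 0, control_batch_loading >= 0,
            noise_sd_M >= 0, sex_effect_sd >= 0, age_effect_sd >= 0,
            height_noise_sd >= 0,
            height_missing_frac >= 0, height_missing_frac <= 1)
  structure(list(planted_dmps = planted_dmps, planted_dmr = planted_dmr,
                 batch_effect_sd = batch_effect_sd,
                 control_batch_loading = control_batch_loading,
                 noise_sd_M = noise_sd_M, sex_effect_sd = sex_effect_sd,
                 age_effect_sd = age_effect_sd,
                 n_nonbimodal = as.integer(n_nonbimodal),
                 n_failed_probes = as.integer(n_failed_probes),
                 height_coefficients = height_coefficients,
                 height_noise_sd = height_noise_sd,
                 height_missing_frac = height_missing_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic methylation dataset
#'
#' Draws beta-values, detection p-values and control-probe intensities for
#' the samples in `sample_sheet` over the signal and control probes of
#' `manifest`, under the generative model described in [sim_config()].
#' Probe baselines are bimodal (mostly strongly methylated or strongly
#' unmethylated), giving each normal sample the characteristic bi-peak
#' beta distribution. Batch enters signal M-values and log2 control
#' intensities through a shared per-sample latent factor. With the same
#' manifest, sample sheet and config (including seed) the output is
#' bit-identical.
#'
#' @param manifest A `probe_manifest`.
#' @param sample_sheet A `sample_sheet`.
#' @param config A `sim_config`.
#' @return Object of class `methylation_dataset`: list with `beta`,
#'   `detection_p` (samples x signal probes), `control_intensities`
#'   (samples x control probes), `sample_sheet`, `manifest`,
#'   `qc_state = "raw"` and attribute `truth` (planted per-probe group
#'   effects on the M scale).
#' @export
generate_methylation <- function(manifest, sample_sheet, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sig <- signal_probes(manifest)
  ctrl <- manifest[manifest$probe_class == "control", , drop = FALSE]
  n <- nrow(sample_sheet)
  p <- nrow(sig)
  if (n == 0L || p == 0L) stop("empty sample sheet or manifest")

  delta <- stats::setNames(rep(0, p), sig$probe_id)
  if (!is.null(config$planted_dmps)) {
    pd <- config$planted_dmps
    if (!all(pd$probe_id %in% sig$probe_id))
      stop("planted probes not present in manifest")
    delta[pd$probe_id] <- pd$delta_M
  }
  if (!is.null(config$planted_dmr)) {
    pr <- config$planted_dmr
    idx_gene <- which(sig$gene == pr$gene)
    if (length(idx_gene) < max(pr$sites))
      stop("planted DMR sites exceed gene size")
    delta[idx_gene[pr$sites]] <- delta[idx_gene[pr$sites]] + pr$delta_M
  }

  # bimodal probe baselines on the M scale
  comp <- sample(1:3, p, TRUE, prob = c(0.45, 0.45, 0.10))
  mu <- numeric(p)
  mu[comp == 1] <- stats::rnorm(sum(comp == 1), -3, 0.7)
  mu[comp == 2] <- stats::rnorm(sum(comp == 2),  3, 0.7)
  mu[comp == 3] <- stats::rnorm(sum(comp == 3),  0, 1.0)

  beta_sex <- stats::rnorm(p, 0, config$sex_effect_sd)
  beta_age <- stats::rnorm(p, 0, config$age_effect_sd)
  load_sig <- stats::rnorm(p, 1, 0.3)

  batch_lv <- sort(unique(sample_sheet$batch))
  batch_score <- stats::setNames(stats::rnorm(length(batch_lv)), batch_lv)
  f <- batch_score[sample_sheet$batch]            # per-sample latent factor

  grp <- as.numeric(sample_sheet$group == "patient")
  sexm <- as.numeric(sample_sheet$sex == "male")
  age_c <- sample_sheet$age_at_followup -
    mean(sample_sheet$age_at_followup)

  M <- matrix(mu, n, p, byrow = TRUE) +
    outer(grp, delta) +
    outer(sexm, beta_sex) +
    outer(age_c, beta_age) +
    config$batch_effect_sd * outer(unname(f), load_sig) +
    matrix(stats::rnorm(n * p, 0, config$noise_sd_M), n, p)
  beta <- 2^M / (2^M + 1)

  detection_p <- matrix(stats::runif(n * p, 0, 1e-3), n, p)
  if (config$n_failed_probes > 0) {
    fail <- sample(p, min(config$n_failed_probes, p))
    detection_p[, fail] <- stats::runif(n * length(fail), 0.05, 1)
  }
  if (config$n_nonbimodal > 0) {
    nb <- sample(n, min(config$n_nonbimodal, n))
    beta[nb, ] <- stats::runif(length(nb) * p, 0.15, 0.85)
  }

  nc <- nrow(ctrl)
  mu_c <- ifelse(ctrl$control_category == "negative",
                 stats::rnorm(nc, 6, 0.5), stats::rnorm(nc, 12, 1))
  load_c <- ifelse(ctrl$control_category == "negative", 0,
                   stats::rnorm(nc, 1, 0.3))
  log2I <- matrix(mu_c, n, nc, byrow = TRUE) +
    config$control_batch_loading * outer(unname(f), load_c) +
    matrix(stats::rnorm(n * nc, 0, 0.15), n, nc)
  control_intensities <- 2^log2I

  dimnames(beta) <- dimnames(detection_p) <-
    list(sample_sheet$sample_id, sig$probe_id)
  dimnames(control_intensities) <- list(sample_sheet$sample_id,
                                        ctrl$probe_id)
  structure(list(beta = beta, detection_p = detection_p,
                 control_intensities = control_intensities,
                 sample_sheet = sample_sheet, manifest = manifest,
                 qc_state = "raw"),
            truth = list(delta_M = delta, batch_factor = unname(f)),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("methylation_dataset:", nrow(x$beta), "samples x", ncol(x$beta),
      "signal probes (", x$qc_state, ")\n")
  cat("  groups:", paste(names(table(x$sample_sheet$group)),
                         table(x$sample_sheet$group), collapse = ", "), "\n")
  cat("  control probes:", ncol(x$control_intensities), "\n")
  invisible(x)
}
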