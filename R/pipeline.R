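#' Default pipeline configuration
#'
#' Every threshold the analysis uses surfaces here with its default. QC and
#' kernel defaults that the underlying methodology leaves open (bimodality
#' window/threshold, detection-p cutoffs, kernel scale factor) are package
#' choices, configurable per run.
#'
#' @param seed Master seed; stage generators derive small offsets from it.
#' @param n_patients,n_healthy Cohort sizes (defaults 818 / 392).
#' @param k_pcs Control-probe principal components used as technical
#'   covariates (default 30).
#' @param fdr_threshold FDR for DMPs and kernel estimates (default 0.05).
#' @param lambda,C,min_cpgs,max_gap Region-detection parameters.
#' @param age_cutoff Age-at-exposure dichotomy in years (default 6).
#' @param cv_folds,cv_iterations,cv_alpha,fold_scheme Robustness-procedure
#'   settings.
#' @param det_p_threshold,fail_fraction,mid_fraction_threshold QC settings.
#' @param normalize Apply between-sample quantile normalization of betas
#'   (default FALSE for synthetic data).
#' @param sim A `sim_config` for the generator stage (seeded from `seed`
#'   when NULL).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 818L, n_healthy = 392L,
                            k_pcs = 30L, fdr_threshold = 0.05,
                            lambda = 1000, C = 2, min_cpgs = 2L,
                            max_gap = 1000, age_cutoff = 6,
                            cv_folds = 10L, cv_iterations = 100L,
                            cv_alpha = 0.05,
                            fold_scheme = "residualise",
                            det_p_threshold = 0.01, fail_fraction = 0.01,
                            mid_fraction_threshold = 0.35,
                            normalize = FALSE, sim = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed + 10L)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulation, sample and probe QC, control-probe PCA, DMP and DMR
#' detection, sex/age interaction and glucocorticoid contrasts on the
#' identified DMPs, and the cross-validated robustness analysis of the
#' methylation-height association. Writes every stage's table to `out_dir`
#' together with a machine-readable run manifest (settings, seeds,
#' versions); rerunning with an identical config reproduces byte-identical
#' tables.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory.
#' @param quiet Suppress stage logging (default FALSE).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[methpanel] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("simulate: manifest + cohort (", config$n_patients, " patients, ",
      config$n_healthy, " healthy)")
  res <- list()
  res$manifest <- stage("simulate",
    generate_manifest(seed = config$seed + 1L))
  res$cohort <- stage("simulate",
    generate_cohort(config$n_patients, config$n_healthy,
                    seed = config$seed + 2L))
  res$dataset <- stage("simulate",
    generate_methylation(res$manifest, res$cohort, config$sim))
  res$dataset$sample_sheet <- stage("simulate",
    generate_height(res$dataset$sample_sheet, res$dataset, config$sim))

  say("preprocess: sample QC, probe filters, ", config$k_pcs,
      " control-probe PCs")
  sqc <- stage("preprocess", assess_sample_quality(
    res$dataset, mid_fraction_threshold = config$mid_fraction_threshold))
  ds <- stage("preprocess", apply_sample_qc(res$dataset, sqc))
  pf <- stage("preprocess", filter_probes(
    ds, det_p_threshold = config$det_p_threshold,
    fail_fraction = config$fail_fraction))
  ds <- pf$dataset
  if (config$normalize) ds$beta <- quantile_normalize_betas(ds$beta)
  res$qc_report <- rbind(as.data.frame(sqc), as.data.frame(pf$report))
  say("preprocess: ", nrow(ds$beta), " samples, ", ncol(ds$beta),
      " probes retained")
  res$pcs <- stage("preprocess", compute_control_pcs(ds, k = config$k_pcs))
  res$dataset_filtered <- ds

  say("dmp: moderated per-CpG models")
  design <- stage("dmp", build_design_matrix(
    ds$sample_sheet, pcs = res$pcs,
    covariates = c("age_at_followup", "centre", "sex",
                   "race_noncaucasian", "origin_noneuropean",
                   "malignancy", "syndrome")))
  res$dmp <- stage("dmp", identify_dmps(ds, design,
                                        fdr_threshold = config$fdr_threshold))
  say("dmp: ", nrow(res$dmp$dmps), " DMPs at FDR < ", config$fdr_threshold)

  say("dmr: kernel-smoothed region detection")
  res$dmr <- stage("dmr", find_dmrs(
    res$dmp, lambda = config$lambda, C = config$C,
    fdr_threshold = config$fdr_threshold, max_gap = config$max_gap,
    min_cpgs = config$min_cpgs))
  say("dmr: ", nrow(res$dmr$regions), " regions")

  dmp_probes <- res$dmp$dmps$probe_id
  dmp_logfc <- stats::setNames(res$dmp$dmps$logFC_M, dmp_probes)
  if (length(dmp_probes) > 0) {
    say("subgroups: interactions + glucocorticoid contrast on ",
        length(dmp_probes), " DMPs")
    res$interaction_sex <- stage("subgroups", test_interaction(
      ds, dmp_probes, "sex", pcs = res$pcs))
    res$interaction_age <- stage("subgroups", test_interaction(
      ds, dmp_probes, "age_ge6", pcs = res$pcs,
      age_cutoff = config$age_cutoff))
    res$gc_effect <- stage("subgroups", test_gc_effect(
      ds, dmp_probes, dmp_logfc, pcs = res$pcs))

    say("height: CV-Fisher robustness (", config$cv_iterations,
        " iterations x ", config$cv_folds, " folds)")
    pat <- ds$sample_sheet$group == "patient"
    hdesign <- stage("height", build_design_matrix(
      ds$sample_sheet[pat, , drop = FALSE], pcs = res$pcs,
      covariates = c("age_at_followup", "centre", "sex",
                     "race_noncaucasian", "origin_noneuropean",
                     "malignancy", "syndrome", "pim3", "pelod",
                     "randomisation_arm", "strongkids", "diagnosis"),
      group_var = NULL))
    rows <- attr(hdesign, "rows_kept")
    pid <- ds$sample_sheet$sample_id[pat][rows]
    M <- beta_to_m(ds$beta[pid, dmp_probes, drop = FALSE])
    res$robustness <- stage("height", cv_fisher_robustness(
      ds$sample_sheet$height_4y[pat][rows], M, hdesign,
      n_folds = config$cv_folds, n_iterations = config$cv_iterations,
      alpha = config$cv_alpha, seed = config$seed + 20L,
      fold_scheme = config$fold_scheme))
    res$robustness <- label_directions(res$robustness, dmp_logfc)
  } else {
    say("subgroups/height: no DMPs; writing empty tables")
    res$interaction_sex <- res$interaction_age <- res$gc_effect <-
      data.frame()
    res$robustness <- structure(
      data.frame(probe_id = character(),
                 pct_significant_iterations = numeric(),
                 fisher_p_median = numeric(), fisher_p_q25 = numeric(),
                 fisher_p_q75 = numeric(), robust = logical(),
                 mean_coefficient = numeric(),
                 direction_label = character()),
      class = c("robustness_records", "data.frame"))
  }

  say("write: tables -> ", out_dir)
  write_tsv(res$qc_report, file.path(out_dir, "qc_report.tsv"))
  write_tsv(res$dmp$table, file.path(out_dir, "dmp_all_probes.tsv"))
  write_tsv(res$dmp$dmps, file.path(out_dir, "dmp_table.tsv"))
  gs <- summarize_by_gene(res$dmp$dmps, res$manifest)
  write_tsv(gs$gene_table, file.path(out_dir, "gene_summary.tsv"))
  write_tsv(as.data.frame(res$dmr$regions),
            file.path(out_dir, "dmr_table.tsv"))
  write_dmr_bed(res$dmr$regions, file.path(out_dir, "dmrs.bed"))
  write_tsv(res$interaction_sex,
            file.path(out_dir, "interaction_sex.tsv"))
  write_tsv(res$interaction_age,
            file.path(out_dir, "interaction_age.tsv"))
  write_tsv(res$gc_effect, file.path(out_dir, "gc_effect.tsv"))
  write_tsv(res$robustness, file.path(out_dir, "robustness_table.tsv"))

  manifest <- list(
    package = "methpanel",
    package_version = as.character(utils::packageVersion("methpanel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    settings = unclass(config)[setdiff(names(config), "sim")],
    sim = unclass(config$sim))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(res)
}
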