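test_that("build_design_matrix counts and validates columns", {
  set.seed(1)
  n <- 40
  sheet <- data.frame(
    sample_id = sprintf("S%02d", 1:n),
    group = rep(c("patient", "healthy"), each = n / 2),
    sex = sample(c("male", "female"), n, TRUE),
    centre = sample(c("A", "B"), n, TRUE),
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
    only = "one", stringsAsFactors = FALSE)
  pcs <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(sheet$sample_id, c("PC1", "PC2")))

  # 1 intercept + 1 group + 1 sex + 1 centre + 3 numeric + 2 PCs = 9
  d <- build_design_matrix(sheet, pcs = pcs,
                           covariates = c("sex", "centre", "x1", "x2", "x3"))
  expect_equal(ncol(d), 9)
  expect_true(all(c("(Intercept)", "grouppatient", "sexmale", "PC1") %in%
                  colnames(d)))

  # empty covariates, no PCs: intercept + group only
  d0 <- build_design_matrix(sheet)
  expect_equal(colnames(d0), c("(Intercept)", "grouppatient"))

  # single-level categorical dropped with a warning, not an error
  expect_warning(d1 <- build_design_matrix(sheet, covariates = "only"),
                 "single level")
  expect_equal(ncol(d1), 2)

  # collinear columns named in the error
  sheet$dup <- sheet$x1
  expect_error(build_design_matrix(sheet, covariates = c("x1", "dup")),
               "collinear.*dup")

  # complete-case guard
  sheet$x1[1:10] <- NA
  expect_error(build_design_matrix(sheet, covariates = "x1"), "drop")
})

test_that("identify_dmps detects planted effects with correct labelling", {
  man <- generate_manifest(4, 20, 60, seed = 2, snp_fraction = 0)
  sig <- signal_probes(man)
  planted <- sig$probe_id[c(3, 17, 41)]
  cfg <- sim_config(planted_dmps = data.frame(probe_id = planted,
                                              delta_M = c(-0.5, -0.5, 0.5)),
                    seed = 3)
  coh <- generate_cohort(400, 200, seed = 4)
  ds <- generate_methylation(man, coh, cfg)
  pf <- filter_probes(ds)
  pcs <- compute_control_pcs(pf$dataset, k = 10)
  design <- build_design_matrix(
    pf$dataset$sample_sheet, pcs = pcs,
    covariates = c("age_at_followup", "centre", "sex"))
  res <- identify_dmps(pf$dataset, design)

  expect_setequal(res$dmps$probe_id, planted)
  expect_equal(res$dmps$direction[match(planted, res$dmps$probe_id)],
               c("hypomethylated", "hypomethylated", "hypermethylated"))
  # invariants
  expect_true(all(res$table$q_bh >= res$table$p_raw - 1e-12))
  expect_true(all(res$table$abs_mean_beta_diff >= 0 &
                  res$table$abs_mean_beta_diff <= 1))
  expect_true(all((res$table$logFC_M < 0) ==
                  (res$table$direction == "hypomethylated")))

  # output invariant to sample ordering
  perm <- sample(nrow(ds$beta))
  ds_p <- ds
  ds_p$beta <- ds$beta[perm, ]
  ds_p$detection_p <- ds$detection_p[perm, ]
  ds_p$control_intensities <- ds$control_intensities[perm, ]
  ds_p$sample_sheet <- ds$sample_sheet[perm, ]
  pf_p <- filter_probes(ds_p)
  pcs_p <- compute_control_pcs(pf_p$dataset, k = 10)
  design_p <- build_design_matrix(
    pf_p$dataset$sample_sheet, pcs = pcs_p,
    covariates = c("age_at_followup", "centre", "sex"))
  res_p <- identify_dmps(pf_p$dataset, design_p)
  expect_equal(res_p$table$logFC_M, res$table$logFC_M, tolerance = 1e-8)

  expect_error(identify_dmps(pf$dataset, design[1:10, ]), "align")
})

test_that("planted logFC is estimated close to truth on the M scale", {
  man <- generate_manifest(3, 15, 60, seed = 5, snp_fraction = 0)
  sig <- signal_probes(man)
  probe <- sig$probe_id[10]
  cfg <- sim_config(planted_dmps = data.frame(probe_id = probe,
                                              delta_M = -0.4), seed = 6)
  coh <- generate_cohort(500, 250, seed = 7)
  ds <- generate_methylation(man, coh, cfg)
  pcs <- compute_control_pcs(ds, k = 10)
  design <- build_design_matrix(ds$sample_sheet, pcs = pcs,
                                covariates = c("age_at_followup", "sex"))
  res <- identify_dmps(ds, design)
  row <- res$table[res$table$probe_id == probe, ]
  expect_lt(abs(row$logFC_M + 0.4), 0.12)
  expect_true(row$ci_lo < -0.4 + 0.15 && row$ci_hi > -0.4 - 0.15)
})

test_that("empirical FDR on a 10%-non-null mixture stays below 0.10", {
  man <- generate_manifest(seed = 71)
  sig <- signal_probes(man)
  set.seed(72)
  nonnull <- sample(sig$probe_id, round(0.10 * nrow(sig)))
  planted <- data.frame(probe_id = nonnull,
                        delta_M = sample(c(-0.3, 0.3), length(nonnull),
                                         TRUE))
  coh <- generate_cohort(818, 392, seed = 73)
  fdp <- numeric(10)
  for (i in 1:10) {
    ds <- generate_methylation(man, coh,
                               sim_config(planted_dmps = planted,
                                          seed = 7000 + i))
    pcs <- compute_control_pcs(ds, k = 30)
    design <- build_design_matrix(
      ds$sample_sheet, pcs = pcs,
      covariates = c("age_at_followup", "centre", "sex"))
    res <- identify_dmps(ds, design)
    disc <- res$dmps$probe_id
    fdp[i] <- sum(!(disc %in% nonnull)) / max(1, length(disc))
  }
  expect_lte(mean(fdp), 0.10)
})

test_that("summarize_by_gene reproduces published percentages", {
  dmps <- published_dmps()
  sm <- summarize_by_gene(dmps, steroid_panel())

  expect_equal(sm$direction$n_hypo, 20)
  expect_equal(sm$direction$pct_hypo, 87.0)
  expect_equal(sm$pct_genes, 42.9)
  expect_equal(length(sm$genes_with_dmp), 12)
  hsd <- sm$gene_table[sm$gene_table$gene == "HSD17B2", ]
  expect_equal(hsd$n_dmp, 8)
  expect_equal(hsd$pct, 25.0)

  # zero DMPs: all percentages 0.0
  none <- summarize_by_gene(dmps[0, ], steroid_panel())
  expect_true(all(none$gene_table$pct == 0))
  expect_equal(none$direction$pct_hypo, 0.0)
  expect_equal(none$pct_genes, 0.0)
})
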