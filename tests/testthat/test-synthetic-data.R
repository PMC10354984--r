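test_that("generate_manifest builds the stated panel and is deterministic", {
  man <- generate_manifest(n_genes = 28, sites_per_gene = steroid_panel(),
                           n_control = 600, seed = 1)
  sig <- signal_probes(man)
  expect_equal(nrow(sig), 627)
  expect_equal(length(unique(sig$gene)), 28)
  expect_equal(sum(steroid_panel()), 627)

  # determinism
  man2 <- generate_manifest(n_genes = 28, sites_per_gene = steroid_panel(),
                            n_control = 600, seed = 1)
  expect_identical(man, man2)

  # invariants: positions positive; signal probes carry no control category;
  # controls include a negative category
  expect_true(all(man$position > 0))
  expect_true(all(sig$control_category == "none"))
  ctrl <- man[man$probe_class == "control", ]
  expect_true("negative" %in% ctrl$control_category)

  # promoter sites lie within 1500 bp upstream of their gene's TSS
  genes <- attr(man, "genes")
  tss <- genes$tss[match(sig$gene, genes$gene)]
  prom <- grepl("Promoter", sig$gene_section)
  expect_true(all(sig$position[prom] >= tss[prom] - 1500 &
                  sig$position[prom] < tss[prom]))

  # gap mixture straddles the 1000-bp grouping distance
  gaps <- unlist(lapply(split(sig$position, sig$gene), diff))
  expect_gt(sum(gaps < 1000), 0)
  expect_gt(sum(gaps > 1000), 0)

  # single-probe gene: deterministic section from position
  m1 <- generate_manifest(1, 1, 1, seed = 5)
  s1 <- signal_probes(m1)
  expect_equal(nrow(s1), 1)
  expect_true(grepl("Promoter|Body|UTR|Exon", s1$gene_section))

  expect_error(generate_manifest(0, 5, 5), ">= 1")
})

test_that("generate_cohort marginals and missingness structure", {
  coh <- generate_cohort(818, 392, seed = 7)
  expect_equal(nrow(coh), 1210)
  pat <- coh[coh$group == "patient", ]
  hea <- coh[coh$group == "healthy", ]

  # GC-treated count near 210/818
  expect_lt(abs(sum(pat$gc_treatment) - 210), 3 * sqrt(818 * 0.257 * 0.743))

  # male fraction within binomial sampling error of the 58.1% target
  se <- sqrt(0.581 * 0.419 / 818)
  expect_lt(abs(mean(pat$sex == "male") - 0.581), 4 * se)

  # healthy rows have PICU-only fields missing
  picu_only <- c("pim3", "pelod", "strongkids", "randomisation_arm",
                 "diagnosis", "gc_treatment", "picu_los")
  for (f in picu_only) expect_true(all(is.na(hea[[f]])), info = f)
  for (f in picu_only) expect_true(all(!is.na(pat[[f]])), info = f)

  expect_true(all(coh$age_at_followup >= 0))
  expect_true(all(pat$age_at_admission >= 0))
  expect_true(mean(pat$strongkids == "medium") > 0.8)

  # patients-only cohort edge
  h5 <- generate_cohort(0, 5, seed = 3)
  expect_equal(nrow(h5), 5)
  expect_true(all(is.na(h5$pim3)))

  expect_identical(generate_cohort(20, 10, seed = 9),
                   generate_cohort(20, 10, seed = 9))
  expect_error(generate_cohort(-1, 5), ">= 0")
})

test_that("generate_methylation honours the generative model", {
  man <- small_manifest()
  coh <- generate_cohort(800, 400, seed = 1)

  # null config: group-wise mean beta difference ~ 0 at every probe
  ds0 <- generate_methylation(man, coh, sim_config(seed = 2))
  grp <- coh$group == "patient"
  d0 <- colMeans(ds0$beta[grp, ]) - colMeans(ds0$beta[!grp, ])
  expect_lt(max(abs(d0)), 0.05)

  # planted delta_M = -0.2: empirical beta difference matches the
  # closed-form logistic difference within sampling error
  sig <- signal_probes(man)
  probe <- sig$probe_id[3]
  cfg <- sim_config(planted_dmps = data.frame(probe_id = probe,
                                              delta_M = -0.2), seed = 2)
  ds <- generate_methylation(man, coh, cfg)
  M_hea <- beta_to_m(ds$beta[!grp, probe])
  mu_hat <- mean(M_hea)
  expected_diff <- m_to_beta(mu_hat - 0.2) - m_to_beta(mu_hat)
  observed_diff <- mean(ds$beta[grp, probe]) - mean(ds$beta[!grp, probe])
  expect_lt(observed_diff, 0)
  expect_lt(abs(observed_diff - expected_diff), 0.02)

  # seeded determinism, bounds, dimensions
  ds2 <- generate_methylation(man, coh, cfg)
  expect_identical(ds$beta, ds2$beta)
  expect_true(all(ds$beta >= 0 & ds$beta <= 1))
  expect_true(all(ds$control_intensities > 0))
  expect_equal(dim(ds$beta), dim(ds$detection_p))
  expect_equal(nrow(ds$beta), nrow(ds$control_intensities))

  expect_error(generate_methylation(
    man, coh, sim_config(planted_dmps = data.frame(probe_id = "nope",
                                                   delta_M = 1))),
    "not present")
})

test_that("generate_height plants recoverable coefficients", {
  man <- small_manifest()
  sig <- signal_probes(man)
  coh <- generate_cohort(818, 0, seed = 5)
  probe <- sig$probe_id[7]

  # zero coefficients: regression slope of height on methylation ~ 0
  cfg0 <- sim_config(seed = 6, height_missing_frac = 0)
  ds <- generate_methylation(man, coh, cfg0)
  sh0 <- generate_height(coh, ds, cfg0)
  m <- beta_to_m(ds$beta[, probe])
  age4 <- coh$age_at_admission + 4
  f0 <- summary(stats::lm(sh0$height_4y ~ age4 + m))
  expect_gt(f0$coefficients["m", "Pr(>|t|)"], 0.01)

  # +3 cm per M-unit recovered within its CI at n = 658
  cfg3 <- sim_config(seed = 6,
                     height_coefficients = stats::setNames(3, probe),
                     height_missing_frac = 160 / 818)
  sh3 <- generate_height(coh, ds, cfg3)
  expect_gt(sum(!is.na(sh3$height_4y)), 600)
  f3 <- summary(stats::lm(sh3$height_4y ~ age4 + I(age4^2) + coh$sex + m))
  est <- f3$coefficients["m", ]
  expect_lt(abs(est["Estimate"] - 3), 2 * est["Std. Error"] + 0.3)

  # determinism; healthy rows untouched
  expect_identical(sh3$height_4y, generate_height(coh, ds, cfg3)$height_4y)
  mix <- generate_cohort(10, 10, seed = 1)
  dmix <- generate_methylation(man, mix, cfg0)
  hmix <- generate_height(mix, dmix, cfg0)
  expect_true(all(is.na(hmix$height_4y[hmix$group == "healthy"])))
})
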