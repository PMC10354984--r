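test_that("kernel_smooth matches hand-computed weights and limits", {
  # constant statistics: S equals t^2 everywhere
  ks <- kernel_smooth(c(0, 100, 300), c(2, 2, 2), lambda = 1000, C = 2)
  expect_equal(ks$S, rep(4, 3), tolerance = 1e-12)

  # isolated site: self-weight only
  ks2 <- kernel_smooth(c(0, 5000), c(1.5, 3), lambda = 1000, C = 2)
  expect_equal(ks2$S, c(1.5^2, 9), tolerance = 1e-12)
  expect_equal(ks2$sumw, c(1, 1))

  # 3 sites at 0/100/200, t = (0,2,0): direct evaluation of the weights
  sigma <- 1000 / 2
  w100 <- exp(-100^2 / (2 * sigma^2))
  w200 <- exp(-200^2 / (2 * sigma^2))
  ks3 <- kernel_smooth(c(0, 100, 200), c(0, 2, 0), lambda = 1000, C = 2)
  expect_equal(ks3$S[2], 4 * 1 / (1 + 2 * w100), tolerance = 1e-12)
  expect_equal(ks3$S[1], 4 * w100 / (1 + w100 + w200), tolerance = 1e-12)

  # truncation beyond lambda: site 3 has both neighbours > 1000 bp away,
  # so only its self-weight contributes
  ks4 <- kernel_smooth(c(0, 999, 2000), c(0, 2, 0), lambda = 1000, C = 2)
  expect_equal(ks4$sumw[3], 1, tolerance = 1e-12)
  expect_equal(ks4$S[3], 0, tolerance = 1e-12)
  # invariance under position translation
  ks5 <- kernel_smooth(c(0, 100, 200) + 1e7, c(0, 2, 0), 1000, 2)
  expect_equal(ks5$S, ks3$S, tolerance = 1e-12)

  expect_error(kernel_smooth(c(5, 1), c(1, 1)), "sorted")
  expect_error(kernel_smooth(c(1, 5), c(1, 1), lambda = -1), "positive")
})

test_that("null_pvalues is calibrated and reduces to chi-square(1)", {
  # isolated site: p = upper-tail chisq(1) of t^2
  t <- 1.7
  np <- null_pvalues(kernel_smooth(c(0), t, 1000, 2))
  expect_equal(np$p, pchisq(t^2, 1, lower.tail = FALSE), tolerance = 1e-12)

  # equal weights over m independent sites: effective df m
  ks <- data.frame(S = 1.2, sumw = 5, sumw2 = 5)
  np2 <- null_pvalues(ks)
  expect_equal(np2$p, pchisq(5 * 1.2, df = 5, lower.tail = FALSE),
               tolerance = 1e-12)

  # calibration: blocks of 3 sites, far apart so blocks are independent;
  # take the centre-site p of each block, expect uniformity (KS, alpha .01)
  set.seed(31)
  B <- 10000
  pos <- as.vector(outer(c(0, 100, 200), (1:B) * 10000, "+"))
  tt <- rnorm(3 * B)
  ks3 <- kernel_smooth(sort(pos), tt, lambda = 1000, C = 2)
  centre <- seq(2, 3 * B, by = 3)
  p <- null_pvalues(ks3)$p[centre]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)

  expect_error(null_pvalues(data.frame(S = 1, sumw = 0, sumw2 = 0)),
               "weight")
})

test_that("group_regions matches brute-force chaining", {
  # worked example: 100/500/1400/3000, gap 1000, min 2
  sites <- data.frame(probe_id = paste0("p", 1:4), chromosome = "chr1",
                      position = c(100, 500, 1400, 3000),
                      logFC_M = c(-1, -1, -1, -1), q_bh = 0.01)
  r <- group_regions(sites, max_gap = 1000, min_cpgs = 2)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 100)
  expect_equal(r$end, 1400)
  expect_equal(r$width, 1300)
  expect_equal(r$n_cpgs, 3)

  # boundary inclusive at exactly 1000 bp
  two <- data.frame(probe_id = c("a", "b"), chromosome = "chr2",
                    position = c(0, 1000), logFC_M = c(1, 1), q_bh = 0.01)
  r2 <- group_regions(two, 1000, 2)
  expect_equal(r2$n_cpgs, 2)

  # empty input
  expect_equal(nrow(group_regions(sites[0, ], 1000, 2)), 0)

  # randomized comparison against the transitive-closure oracle
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(50, 1)
    pos <- sort(sample(1e5, n))
    s <- data.frame(probe_id = paste0("p", 1:n), chromosome = "chrX",
                    position = pos, logFC_M = rnorm(n), q_bh = 0.01)
    got <- group_regions(s, 1000, 1)
    comp <- group_oracle(pos, 1000)
    expect_equal(nrow(got), length(unique(comp)))
    sizes_got <- sort(got$n_cpgs)
    sizes_orc <- sort(as.integer(table(comp)))
    expect_equal(sizes_got, sizes_orc)
  }
})

test_that("find_dmrs recovers an isolated planted region", {
  man <- generate_manifest(3, 15, 60, seed = 8, snp_fraction = 0)
  man <- isolate_gene_run(man, "GENE02", 5:9)
  cfg <- sim_config(planted_dmr = list(gene = "GENE02", sites = 5:9,
                                       delta_M = 0.5), seed = 9)
  coh <- generate_cohort(800, 400, seed = 10)
  ds <- generate_methylation(man, coh, cfg)
  pcs <- compute_control_pcs(ds, k = 10)
  design <- build_design_matrix(ds$sample_sheet, pcs = pcs,
                                covariates = c("age_at_followup", "sex"))
  dmp <- identify_dmps(ds, design)
  dmr <- find_dmrs(dmp)

  sig <- signal_probes(man)
  planted_ids <- sig$probe_id[sig$gene == "GENE02"][5:9]
  members <- strsplit(dmr$regions$member_probe_ids, ";")
  hit <- vapply(members, function(m) setequal(m, planted_ids), logical(1))
  expect_true(any(hit))
  reg <- dmr$regions[hit, ][1, ]
  expect_equal(reg$direction, "hypermethylated")
  pos <- sig$position[match(planted_ids, sig$probe_id)]
  expect_equal(reg$start, min(pos))
  expect_equal(reg$end, max(pos))
  expect_equal(reg$width, max(pos) - min(pos))
})

test_that("write_dmr_bed converts to 0-based half-open coordinates", {
  r <- structure(data.frame(gene = "G", chromosome = "chr1", start = 101L,
                            end = 200L, width = 99L, n_cpgs = 3L,
                            member_probe_ids = "a;b;c",
                            mean_logFC_M = -1, min_q = 0.01,
                            direction = "hypomethylated"),
                 class = c("dmr_records", "data.frame"))
  path <- tempfile(fileext = ".bed")
  write_dmr_bed(r, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 200)
})
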