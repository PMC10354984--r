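# Small in-code fixtures shared across the suite.

small_manifest <- function(seed = 1, n_genes = 4, sites = 10, controls = 40) {
  generate_manifest(n_genes = n_genes, sites_per_gene = sites,
                    n_control = controls, seed = seed, snp_fraction = 0)
}

small_dataset <- function(seed = 1, n_pat = 60, n_hea = 30, config = NULL,
                          manifest = small_manifest(seed)) {
  if (is.null(config)) config <- sim_config(seed = seed + 100)
  cohort <- generate_cohort(n_pat, n_hea, seed = seed + 200)
  generate_methylation(manifest, cohort, config)
}

# Minimal covariate design for a sample sheet (intercept + group only).
minimal_design <- function(sheet) {
  build_design_matrix(sheet, covariates = character())
}

# Brute-force BH step-up: q_(i) = min_{k >= i} m * p_(k) / k, explicit loops.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (k in i:m) best <- min(best, m * ps[k] / k)
    q[i] <- min(best, 1)
  }
  q[order(o)]
}

# Transitive-closure oracle for region grouping: sites are linked when
# within max_gap on the same chromosome; components via closure iteration.
group_oracle <- function(pos, max_gap) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}
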