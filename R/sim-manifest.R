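#' Generate a synthetic probe manifest for a targeted CpG panel
#'
#' Builds a manifest of signal CpG probes clustered within per-gene genomic
#' windows plus a set of array control probes. Each gene is given a synthetic
#' transcription start site (TSS); CpG positions start inside the 1500-bp
#' promoter window upstream of the TSS and walk downstream with inter-site
#' gaps drawn from a mixture (75% short gaps, uniform 20-800 bp; 25% long
#' gaps, uniform 1200-5000 bp), so some gaps fall below and some above the
#' 1000-bp region-grouping distance. Gene sections are assigned
#' deterministically from position relative to the TSS:
#' `[TSS-1500, TSS)` Promoter, `[TSS, TSS+200)` 5'UTR, `[TSS+200, TSS+500)`
#' 1stExon, then Body with the final site labelled 3'UTR; a site within
#' 50 bp of a section boundary receives the compound label of both sections.
#'
#' @param n_genes Number of genes (default 28, the steroidogenesis panel).
#' @param sites_per_gene Single count or per-gene vector of CpG counts
#'   (default [steroid_panel()] when `n_genes` is 28).
#' @param n_control Number of control probes (default 600); control
#'   categories always include `negative`.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   manifest.
#' @param snp_fraction Fraction of signal probes flagged as overlapping a
#'   known SNP (default 0.05).
#' @return Data frame of class `probe_manifest` with columns `probe_id`,
#'   `chromosome`, `position`, `gene`, `gene_section`, `snp_flag`,
#'   `probe_class`, `control_category`, and attribute `genes` (per-gene
#'   chromosome and TSS).
#' @export
generate_manifest <- function(n_genes = 28L, sites_per_gene = NULL,
                              n_control = 600L, seed = 1L,
                              snp_fraction = 0.05) {
  if (n_genes < 1L || n_control < 1L) stop("counts must be >= 1")
  if (is.null(sites_per_gene)) {
    sites_per_gene <- if (n_genes == 28L) steroid_panel() else 20L
  }
  sites_per_gene <- rep_len(as.integer(sites_per_gene), n_genes)
  if (any(sites_per_gene < 1L)) stop("counts must be >= 1")
  gene_names <- if (!is.null(names(sites_per_gene)) &&
                    all(nzchar(names(sites_per_gene)))) {
    names(sites_per_gene)
  } else if (n_genes == 28L && is.null(names(sites_per_gene))) {
    names(steroid_panel())
  } else {
    sprintf("GENE%02d", seq_len(n_genes))
  }
  set.seed(seed)

  chroms <- paste0("chr", ((seq_len(n_genes) - 1L) %% 22L) + 1L)
  slot <- (seq_len(n_genes) - 1L) %/% 22L      # genes sharing a chromosome
  tss <- 2e6 + slot * 5e6 + round(stats::runif(n_genes, 0, 5e5))

  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    ns <- sites_per_gene[g]
    start <- tss[g] - 1500L + round(stats::runif(1, 0, 400))
    gaps <- ifelse(stats::runif(ns - 1L) < 0.75,
                   stats::runif(ns - 1L, 20, 800),
                   stats::runif(ns - 1L, 1200, 5000))
    pos <- start + c(0, cumsum(round(gaps)))
    rows[[g]] <- data.frame(
      chromosome = chroms[g], position = as.integer(pos),
      gene = gene_names[g], gene_section = .gene_section(pos, tss[g]),
      stringsAsFactors = FALSE)
  }
  sig <- do.call(rbind, rows)
  sig$probe_id <- sprintf("cg%08d", seq_len(nrow(sig)))
  sig$snp_flag <- stats::runif(nrow(sig)) < snp_fraction
  sig$probe_class <- "signal"
  sig$control_category <- "none"

  ctrl_cats <- c("negative", "bisulphite_conversion", "staining",
                 "extension", "hybridization", "specificity")
  cats <- rep_len(ctrl_cats, n_control)
  ctrl <- data.frame(
    chromosome = "control", position = seq_len(n_control),
    gene = NA_character_, gene_section = NA_character_,
    probe_id = sprintf("ctrl%05d", seq_len(n_control)),
    snp_flag = FALSE, probe_class = "control", control_category = cats,
    stringsAsFactors = FALSE)

  man <- rbind(sig[, names(ctrl)], ctrl)
  rownames(man) <- NULL
  man <- man[, c("probe_id", "chromosome", "position", "gene",
                 "gene_section", "snp_flag", "probe_class",
                 "control_category")]
  attr(man, "genes") <- data.frame(gene = gene_names, chromosome = chroms,
                                   tss = tss, stringsAsFactors = FALSE)
  class(man) <- c("probe_manifest", "data.frame")
  man
}

# Section from position relative to the TSS; compound label near boundaries.
.gene_section <- function(pos, tss) {
  rel <- pos - tss
  sect <- ifelse(rel < 0, "Promoter",
          ifelse(rel < 200, "5'UTR",
          ifelse(rel < 500, "1stExon", "Body")))
  sect[which.max(rel)] <- if (max(rel) >= 500) "3'UTR" else sect[which.max(rel)]
  near <- rel >= 150 & rel < 200
  sect[near] <- "5'UTR/1stExon"
  near0 <- rel >= -50 & rel < 0
  sect[near0] <- "Promoter/1stExon"
  sect
}

#' Signal-probe subset of a manifest
#' @param manifest A `probe_manifest`.
#' @return Data frame of signal probes only.
#' @export
signal_probes <- function(manifest) {
  manifest[manifest$probe_class == "signal", , drop = FALSE]
}
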