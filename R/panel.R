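#' Steroidogenesis gene panel
#'
#' Per-gene CpG-site counts for the 28-gene steroid biosynthesis and steroid
#' sulphation/desulphation panel (627 CpG sites in total). The twelve genes
#' that harbour differentially methylated positions in the published cohort
#' analysis carry their published site counts; the counts for the remaining
#' sixteen genes were not published per gene and are synthetic stand-ins
#' chosen once to bring the panel total to 627.
#'
#' @return Named integer vector of CpG-site counts per gene; sums to 627.
#' @export
steroid_panel <- function() {
  c(CYP11A1 = 37L, FDX1 = 15L, FDX2 = 12L, FDXR = 20L,
    HSD3B1 = 14L, HSD3B2 = 15L, CYP17A1 = 21L, POR = 69L,
    CYB5A = 28L, CYB5B = 18L, HSD17B1 = 15L, HSD17B2 = 32L,
    HSD17B3 = 19L, HSD17B6 = 10L, HSD17B7 = 16L, HSD17B8 = 17L,
    HSD17B10 = 15L, HSD17B11 = 16L, HSD17B12 = 47L, HSD17B14 = 15L,
    CYP19A1 = 55L, CYP21A2 = 13L, CYP11B1 = 12L, CYP11B2 = 11L,
    SULT2A1 = 14L, SULT2B1 = 30L, SULT1E1 = 12L, STS = 29L)
}

#' Published differentially methylated positions (cohort study)
#'
#' The 23 CpG sites reported as differentially methylated between former
#' PICU patients and healthy children, with gene, gene section, methylation
#' status, adjusted log fold change in M-values with 95% CI, absolute mean
#' beta-value difference, the FDR-adjusted group p-value and the raw
#' interaction (sex, age at exposure) and glucocorticoid-contrast p-values.
#' Shipped as a plain-text table under `extdata`; used as a worked-example
#' input for reporting arithmetic (direction tallies, gene coverage).
#'
#' @return Data frame with 23 rows.
#' @export
published_dmps <- function() {
  path <- system.file("extdata", "published_dmps.tsv", package = "methpanel",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published differentially methylated regions (cohort study)
#'
#' The four regions reported as differentially methylated, with gene, number
#' of member CpG sites, width in base pairs and direction.
#'
#' @return Data frame with 4 rows.
#' @export
published_dmrs <- function() {
  path <- system.file("extdata", "published_dmrs.tsv", package = "methpanel",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
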