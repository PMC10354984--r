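#' Format a log fold change with confidence interval
#'
#' Three decimals, publication layout: `"-0.116 [-0.175 to -0.058]"`.
#'
#' @param logfc,lo,hi Numeric vectors.
#' @return Character vector.
#' @export
fmt_logfc_ci <- function(logfc, lo, hi) {
  sprintf("%.3f [%.3f to %.3f]", logfc, lo, hi)
}

#' Format a percentage to one decimal
#'
#' 100 prints as `"100"`, matching the publication layout.
#'
#' @param x Percentages.
#' @return Character vector.
#' @export
fmt_pct <- function(x) {
  ifelse(abs(x - 100) < 1e-9, "100", sprintf("%.1f", x))
}

#' Format a p-value to two significant figures
#'
#' Fixed notation with trailing zeros kept down to 1e-4 (`0.0090`),
#' scientific below (`2.8e-26`).
#'
#' @param p P-values.
#' @return Character vector.
#' @export
fmt_p <- function(p) {
  ifelse(p >= 1e-4,
         formatC(signif(p, 2), digits = 2, format = "fg", flag = "#"),
         sprintf("%.1e", signif(p, 2)))
}

#' Render publication-style result tables
#'
#' Formats the DMP and robustness results into the column layouts of the
#' published effect-size and height-association tables: log fold change
#' `[CI]` to 3 decimals, percentages to 1 decimal (100 as `"100"`),
#' p-values to 2 significant figures, direction labels verbatim
#' `Hypomethylated` / `Hypermethylated` / `Harm`. Empty inputs yield
#' header-only tables.
#'
#' @param dmp_result A `dmp_result`, or NULL.
#' @param robustness A labelled `robustness_records` data frame (see
#'   [label_directions()]), or NULL.
#' @return List with character-column data frames `dmp_table` and
#'   `robustness_table` (whichever inputs were supplied).
#' @export
render_tables <- function(dmp_result = NULL, robustness = NULL) {
  out <- list()
  if (!is.null(dmp_result)) {
    d <- dmp_result$dmps
    out$dmp_table <- data.frame(
      Gene = d$gene, CpG_site = d$probe_id, Gene_section = d$gene_section,
      Methylation_status = ifelse(d$direction == "hypomethylated",
                                  "Hypomethylated", "Hypermethylated"),
      Log_fold_change_CI = fmt_logfc_ci(d$logFC_M, d$ci_lo, d$ci_hi),
      Absolute_mean_difference = sprintf("%.3f", d$abs_mean_beta_diff),
      P_value = fmt_p(d$q_bh),
      stringsAsFactors = FALSE)
  }
  if (!is.null(robustness)) {
    r <- robustness
    lab <- if ("direction_label" %in% names(r)) r$direction_label
           else rep("none", nrow(r))
    out$robustness_table <- data.frame(
      CpG_site = r$probe_id,
      Pct_significant_iterations = fmt_pct(r$pct_significant_iterations),
      Median_IQR_P = sprintf("%s (%s-%s)", fmt_p(r$fisher_p_median),
                             fmt_p(r$fisher_p_q25), fmt_p(r$fisher_p_q75)),
      Direction = lab,
      stringsAsFactors = FALSE)
  }
  out
}
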