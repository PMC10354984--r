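#' Build the covariate design matrix for per-CpG models
#'
#' Constructs `intercept + group indicator + covariates + control-probe PC
#' columns` with stable, documented column names. Character/factor
#' covariates are dummy-coded against their first level; logicals become
#' 0/1; numerics enter as-is. Single-level categoricals are dropped with a
#' warning. Missing covariate values trigger complete-case analysis, with an
#' error if more than `max_dropped_frac` of samples would be lost.
#'
#' @param sample_sheet A `sample_sheet` (or any data frame with a `group`
#'   column when `group_var` is default).
#' @param pcs A `control_pcs` object, a numeric matrix of technical
#'   covariates, or NULL.
#' @param covariates Character vector of sample-sheet column names.
#' @param group_var Column holding the two-level group factor (default
#'   "group"); its second level after sorting ("patient" for
#'   patient/healthy) is coded 1. NULL omits the group column.
#' @param interaction_var Optional column name: adds the factor's main
#'   effect and its interaction with the group indicator.
#' @param max_dropped_frac Complete-case tolerance (default 0.05).
#' @return Design matrix with attribute `rows_kept` (row indices of
#'   `sample_sheet` retained after complete-case filtering).
#' @export
build_design_matrix <- function(sample_sheet, pcs = NULL,
                                covariates = character(),
                                group_var = "group",
                                interaction_var = NULL,
                                max_dropped_frac = 0.05) {
  n <- nrow(sample_sheet)
  used <- c(covariates, group_var, interaction_var)
  used <- used[!vapply(used, is.null, logical(1))]
  missing_cols <- setdiff(used, names(sample_sheet))
  if (length(missing_cols))
    stop("covariates not in sample sheet: ",
         paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(sample_sheet[, used, drop = FALSE])
  if (mean(!cc) > max_dropped_frac)
    stop(sprintf("complete-case analysis would drop %.1f%% of samples",
                 100 * mean(!cc)))
  sheet <- sample_sheet[cc, , drop = FALSE]

  cols <- list("(Intercept)" = rep(1, nrow(sheet)))
  grp <- NULL
  if (!is.null(group_var)) {
    gv <- as.factor(sheet[[group_var]])
    if (nlevels(gv) != 2L) stop("group variable must have exactly 2 levels")
    grp <- as.numeric(gv == sort(levels(gv))[2])
    cols[[paste0(group_var, sort(levels(gv))[2])]] <- grp
  }
  code1 <- function(x, nm) {
    if (is.numeric(x)) return(stats::setNames(list(x), nm))
    if (is.logical(x)) return(stats::setNames(list(as.numeric(x)), nm))
    f <- as.factor(x)
    if (nlevels(f) < 2L) {
      warning("covariate '", nm, "' has a single level and was dropped")
      return(list())
    }
    lv <- levels(f)[-1]
    out <- lapply(lv, function(l) as.numeric(f == l))
    stats::setNames(out, paste0(nm, lv))
  }
  for (cv in covariates) cols <- c(cols, code1(sheet[[cv]], cv))
  if (!is.null(interaction_var)) {
    fac_cols <- code1(sheet[[interaction_var]], interaction_var)
    for (nm in names(fac_cols)) {
      cols[[nm]] <- fac_cols[[nm]]
      cols[[paste0(group_var, ":", nm)]] <- grp * fac_cols[[nm]]
    }
  }
  design <- do.call(cbind, cols)
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "control_pcs")) pcs$scores else as.matrix(pcs)
    sc <- sc[sheet$sample_id, , drop = FALSE]
    design <- cbind(design, sc)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[seq(qrd$rank + 1L, ncol(design))]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  attr(design, "rows_kept") <- which(cc)
  design
}

#' Identify differentially methylated positions
#'
#' Per signal probe: fit the multivariable linear model on M-values,
#' moderate residual variances jointly across all panel probes, test the
#' group coefficient with the moderated t, and control the FDR across probes
#' with Benjamini-Hochberg. The absolute mean beta difference is the
#' unadjusted difference of group mean beta-values.
#'
#' @param dataset A filtered `methylation_dataset`.
#' @param design Design matrix from [build_design_matrix()] (its
#'   `rows_kept` attribute selects the samples used).
#' @param fdr_threshold FDR cutoff defining a DMP (default 0.05).
#' @param coef Name of the tested coefficient (default "grouppatient").
#' @return Object of class `dmp_result`: list with `table` (all probes:
#'   `probe_id, gene, gene_section, chromosome, position, logFC_M, ci_lo,
#'   ci_hi, t, p_raw, q_bh, direction, abs_mean_beta_diff`), `dmps` (subset
#'   with `q_bh < fdr_threshold`), `fdr_threshold`, `coef` and `moderation`.
#' @export
identify_dmps <- function(dataset, design, fdr_threshold = 0.05,
                          coef = "grouppatient") {
  rows <- attr(design, "rows_kept")
  if (is.null(rows)) rows <- seq_len(nrow(dataset$beta))
  if (nrow(design) != length(rows) ||
      max(rows) > nrow(dataset$beta))
    stop("design rows do not align with dataset samples")
  beta <- dataset$beta[rows, , drop = FALSE]
  M <- beta_to_m(beta)
  fit <- fit_linear_model(M, design)
  mod <- moderate_variances(fit$sigma2, fit$df_residual)
  tt <- moderated_t_test(fit, mod, coef)
  q <- bh_adjust(tt$p)

  sig <- signal_probes(dataset$manifest)
  sig <- sig[match(colnames(beta), sig$probe_id), , drop = FALSE]
  grp <- dataset$sample_sheet$group[rows] == "patient"
  amd <- abs(colMeans(beta[grp, , drop = FALSE]) -
             colMeans(beta[!grp, , drop = FALSE]))

  table <- data.frame(
    probe_id = colnames(beta), gene = sig$gene,
    gene_section = sig$gene_section, chromosome = sig$chromosome,
    position = sig$position,
    logFC_M = tt$coefficient, ci_lo = tt$ci_lo, ci_hi = tt$ci_hi,
    t = tt$t, p_raw = tt$p, q_bh = q,
    direction = ifelse(tt$coefficient < 0, "hypomethylated",
                       "hypermethylated"),
    abs_mean_beta_diff = unname(amd),
    stringsAsFactors = FALSE)
  structure(list(table = table,
                 dmps = table[table$q_bh < fdr_threshold, , drop = FALSE],
                 fdr_threshold = fdr_threshold, coef = coef,
                 moderation = mod, design = design),
            class = "dmp_result")
}

#' One-decimal percentage
#' @param num,den Counts.
#' @return `100 * num / den` rounded to one decimal.
#' @export
pct1 <- function(num, den) round(100 * num / den, 1)

#' Summarize DMPs per gene and tally directions
#'
#' @param dmps Data frame of DMP records (needs `gene` and `direction` or
#'   `status` columns), e.g. the `dmps` element of a `dmp_result` or the
#'   published table.
#' @param manifest A `probe_manifest`, or a named vector of per-gene site
#'   counts such as [steroid_panel()].
#' @return List with `gene_table` (`gene, n_dmp, n_sites, pct` for every
#'   panel gene), `direction` (`n_hypo, n_hyper, pct_hypo, pct_hyper`),
#'   `genes_with_dmp`, `n_genes`, `pct_genes`.
#' @export
summarize_by_gene <- function(dmps, manifest) {
  counts <- if (is.data.frame(manifest)) {
    tab <- table(signal_probes(manifest)$gene)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(as.integer(manifest), names(manifest))
  dir_col <- if ("direction" %in% names(dmps)) dmps$direction else dmps$status
  hypo <- grepl("^hypo", dir_col, ignore.case = TRUE)
  n_dmp <- table(factor(dmps$gene, levels = names(counts)))
  gene_table <- data.frame(
    gene = names(counts),
    n_dmp = as.integer(n_dmp),
    n_sites = unname(counts),
    pct = pct1(as.integer(n_dmp), unname(counts)),
    stringsAsFactors = FALSE)
  genes_hit <- sort(unique(dmps$gene))
  safe_pct <- function(k, n) if (n == 0L) 0.0 else pct1(k, n)
  list(gene_table = gene_table,
       direction = list(n_hypo = sum(hypo), n_hyper = sum(!hypo),
                        pct_hypo = safe_pct(sum(hypo), nrow(dmps)),
                        pct_hyper = safe_pct(sum(!hypo), nrow(dmps))),
       genes_with_dmp = genes_hit,
       n_genes = length(counts),
       pct_genes = pct1(length(genes_hit), length(counts)))
}
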