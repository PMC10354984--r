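#' Beta-value to M-value transform
#'
#' `M = log2(beta / (1 - beta))` after clamping beta into
#' `[epsilon, 1 - epsilon]` to keep the transform finite at the boundaries.
#'
#' @param beta Numeric vector or matrix of methylation proportions in \[0,1\].
#' @param epsilon Clamping constant (default 1e-6).
#' @return M-values with the same shape as `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0,1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' M-value to beta-value transform
#'
#' Exact inverse of [beta_to_m()] on the clamped domain:
#' `beta = 2^M / (2^M + 1)`.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values in \[0,1\].
#' @export
m_to_beta <- function(m) {
  # computed via plogis on the natural-log scale for numerical stability
  stats::plogis(m * log(2))
}

#' Sample quality control
#'
#' Flags samples whose beta distribution lacks the typical bi-peak shape
#' (low- and high-methylation modes): a sample is flagged `non_bimodal` iff
#' the fraction of its beta-values inside the mid-range window exceeds the
#' threshold. Samples with insufficient DNA yield (column `dna_yield_ng` of
#' the sample sheet, when present, below `min_yield_ng`) are flagged
#' `low_yield`; alternatively explicit ids can be supplied.
#'
#' @param dataset A `methylation_dataset`.
#' @param mid_window Beta window counted as mid-range (default (0.25, 0.75)).
#' @param mid_fraction_threshold Flagging threshold for the mid-range
#'   fraction (default 0.35).
#' @param min_yield_ng DNA-yield threshold in ng (default 50).
#' @param low_yield_ids Optional explicit sample ids to flag as low yield.
#' @return Object of class `qc_report`: data frame with columns `id`,
#'   `type` ("sample"), `reason`; thresholds kept as attributes.
#' @export
assess_sample_quality <- function(dataset, mid_window = c(0.25, 0.75),
                                  mid_fraction_threshold = 0.35,
                                  min_yield_ng = 50,
                                  low_yield_ids = character()) {
  if (nrow(dataset$beta) == 0L) stop("empty dataset")
  frac <- rowMeans(dataset$beta > mid_window[1] &
                   dataset$beta < mid_window[2])
  nb <- rownames(dataset$beta)[frac > mid_fraction_threshold]
  ly <- unique(low_yield_ids)
  if (!is.null(dataset$sample_sheet$dna_yield_ng)) {
    ly <- union(ly, dataset$sample_sheet$sample_id[
      dataset$sample_sheet$dna_yield_ng < min_yield_ng])
  }
  bad <- setdiff(ly, rownames(dataset$beta))
  if (length(bad)) stop("unknown sample ids: ", paste(bad, collapse = ", "))
  ids <- c(ly, setdiff(nb, ly))
  rep <- data.frame(
    id = ids,
    type = rep("sample", length(ids)),
    reason = c(rep("low_yield", length(ly)),
               rep("non_bimodal", length(setdiff(nb, ly)))),
    stringsAsFactors = FALSE)
  structure(rep,
            thresholds = list(mid_window = mid_window,
                              mid_fraction_threshold = mid_fraction_threshold,
                              min_yield_ng = min_yield_ng),
            class = c("qc_report", "data.frame"))
}

#' Remove flagged samples from a dataset
#'
#' @param dataset A `methylation_dataset`.
#' @param qc_report A sample `qc_report` from [assess_sample_quality()].
#' @return The dataset without the flagged samples.
#' @export
apply_sample_qc <- function(dataset, qc_report) {
  drop <- unique(qc_report$id[qc_report$type == "sample"])
  keep <- !(rownames(dataset$beta) %in% drop)
  dataset$beta <- dataset$beta[keep, , drop = FALSE]
  dataset$detection_p <- dataset$detection_p[keep, , drop = FALSE]
  dataset$control_intensities <-
    dataset$control_intensities[keep, , drop = FALSE]
  dataset$sample_sheet <-
    dataset$sample_sheet[!(dataset$sample_sheet$sample_id %in% drop), ,
                         drop = FALSE]
  dataset
}

#' Probe quality control
#'
#' Removes (a) background probes: signal probes whose detection p-value
#' exceeds `det_p_threshold` in more than `fail_fraction` of samples, and
#' (b) all SNP-flagged probes. Idempotent: filtering an already-filtered
#' dataset removes nothing further.
#'
#' @param dataset A `methylation_dataset`.
#' @param det_p_threshold Detection p-value cutoff (default 0.01).
#' @param fail_fraction Maximum tolerated fraction of failing samples per
#'   probe (default 0.01).
#' @return List with `dataset` (filtered, `qc_state = "filtered"`) and
#'   `report` (a probe `qc_report` with reasons `background` / `snp`).
#' @export
filter_probes <- function(dataset, det_p_threshold = 0.01,
                          fail_fraction = 0.01) {
  if (det_p_threshold < 0 || det_p_threshold > 1 ||
      fail_fraction < 0 || fail_fraction > 1)
    stop("thresholds must lie in [0,1]")
  sig <- signal_probes(dataset$manifest)
  sig <- sig[sig$probe_id %in% colnames(dataset$beta), , drop = FALSE]
  failfrac <- colMeans(dataset$detection_p > det_p_threshold)
  bg <- colnames(dataset$detection_p)[failfrac > fail_fraction]
  snp <- sig$probe_id[sig$snp_flag]
  ids <- c(bg, setdiff(snp, bg))
  rep <- data.frame(
    id = ids,
    type = rep("probe", length(ids)),
    reason = c(rep("background", length(bg)),
               rep("snp", length(setdiff(snp, bg)))),
    stringsAsFactors = FALSE)
  keep <- setdiff(colnames(dataset$beta), rep$id)
  dataset$beta <- dataset$beta[, keep, drop = FALSE]
  dataset$detection_p <- dataset$detection_p[, keep, drop = FALSE]
  dataset$qc_state <- "filtered"
  structure_rep <- structure(rep,
    thresholds = list(det_p_threshold = det_p_threshold,
                      fail_fraction = fail_fraction),
    class = c("qc_report", "data.frame"))
  list(dataset = dataset, report = structure_rep)
}

#' Principal components of the control probes
#'
#' PCA of the log2 control-probe intensities (centred per probe, unscaled),
#' excluding the listed control categories (by default the negative
#' background controls). The leading score columns serve as technical
#' covariates proxying batch in all downstream models.
#'
#' @param dataset A `methylation_dataset`.
#' @param k Number of components to return (default 30).
#' @param exclude Control categories to drop before the PCA
#'   (default "negative").
#' @return Object of class `control_pcs`: list with `scores` (samples x k,
#'   columns `PC1..PCk`, zero mean), `explained_variance` (proportions, all
#'   components) and `excluded_control_categories`.
#' @export
compute_control_pcs <- function(dataset, k = 30L, exclude = "negative") {
  ctrl <- dataset$manifest[dataset$manifest$probe_class == "control", ,
                           drop = FALSE]
  keep <- ctrl$probe_id[!(ctrl$control_category %in% exclude)]
  X <- log2(dataset$control_intensities[, keep, drop = FALSE])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) stop("degenerate control matrix: no variation")
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank)
    stop("k = ", k, " exceeds the rank (", rank, ") of the control matrix")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(X)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, explained_variance = ev,
                 excluded_control_categories = exclude),
            class = "control_pcs")
}

#' Between-sample quantile normalization of beta-values
#'
#' Optional: maps every sample's beta distribution onto the mean empirical
#' distribution across samples. Off by default in the pipeline, since
#' synthetic data carry no dye bias.
#'
#' @param beta Samples x probes matrix.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize_betas <- function(beta) {
  p <- ncol(beta)
  ref <- colMeans(t(apply(beta, 1, sort)))
  out <- beta
  for (i in seq_len(nrow(beta))) {
    r <- rank(beta[i, ], ties.method = "average")
    out[i, ] <- stats::approx(seq_len(p), ref, xout = r, rule = 2)$y
  }
  out
}
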