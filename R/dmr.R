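#' Gaussian-kernel smoothing of squared per-CpG statistics
#'
#' For each CpG site i, the kernel estimate is the weighted average of the
#' squared statistics of its neighbours,
#' `S_i = sum_j w_ij t_j^2 / sum_j w_ij`, with Gaussian weights
#' `w_ij = exp(-(pos_i - pos_j)^2 / (2 sigma^2))`, `sigma = lambda / C`, and
#' contributions truncated at `|pos_i - pos_j| > lambda`. The per-site sums
#' of weights and squared weights are retained for the moment-matched null.
#'
#' @param positions Sorted base-pair positions within one chromosome.
#' @param t Per-site statistics aligned with `positions`.
#' @param lambda Truncation distance in bp (default 1000).
#' @param C Bandwidth scale factor, `sigma = lambda / C` (default 2).
#' @return Data frame with `S`, `sumw`, `sumw2` per site.
#' @export
kernel_smooth <- function(positions, t, lambda = 1000, C = 2) {
  if (lambda <= 0) stop("lambda must be positive")
  if (is.unsorted(positions)) stop("positions must be sorted")
  if (length(positions) != length(t)) stop("length mismatch")
  n <- length(positions)
  sigma <- lambda / C
  t2 <- t^2
  S <- sumw <- sumw2 <- numeric(n)
  lo <- 1L
  hi <- 1L
  for (i in seq_len(n)) {
    while (positions[i] - positions[lo] > lambda) lo <- lo + 1L
    if (hi < i) hi <- i
    while (hi < n && positions[hi + 1L] - positions[i] <= lambda)
      hi <- hi + 1L
    d <- positions[lo:hi] - positions[i]
    w <- exp(-d^2 / (2 * sigma^2))
    sumw[i] <- sum(w)
    sumw2[i] <- sum(w^2)
    S[i] <- sum(w * t2[lo:hi]) / sumw[i]
  }
  data.frame(S = S, sumw = sumw, sumw2 = sumw2)
}

#' Null p-values for kernel estimates
#'
#' Under the null each squared statistic is treated as chi-square with 1
#' degree of freedom, so `S_i` has mean 1 and variance
#' `2 sum(w^2) / (sum w)^2`. A two-moment (Satterthwaite) scaled chi-square
#' fit gives effective degrees of freedom `nu_i = (sum w)^2 / sum(w^2)` and
#' `p_i = P(chisq_nu > nu_i S_i)`; q-values are Benjamini-Hochberg across
#' sites. An isolated site (self-weight only) reduces exactly to the 1-df
#' chi-square tail of `t^2`.
#'
#' @param smoothed Data frame from [kernel_smooth()] (or vector of kernel
#'   estimates, with `sumw`/`sumw2` supplied separately).
#' @param sumw,sumw2 Per-site weight sums (taken from `smoothed` when it is
#'   a data frame).
#' @return Data frame with `p` and `q_bh` per site.
#' @export
null_pvalues <- function(smoothed, sumw = NULL, sumw2 = NULL) {
  if (is.data.frame(smoothed)) {
    sumw <- smoothed$sumw; sumw2 <- smoothed$sumw2; S <- smoothed$S
  } else S <- smoothed
  if (any(sumw <= 0)) stop("zero kernel weight sum")
  nu <- sumw^2 / sumw2
  p <- stats::pchisq(nu * S, df = nu, lower.tail = FALSE)
  data.frame(p = p, q_bh = bh_adjust(p))
}

#' Group significant sites into regions
#'
#' Single-linkage chaining of significant CpG sites within a chromosome:
#' consecutive sites at most `max_gap` base pairs apart (boundary inclusive)
#' belong to the same region; regions with fewer than `min_cpgs` members are
#' dropped. The two extreme member CpGs determine the region location and
#' width (`width = end - start`).
#'
#' @param sites Data frame of significant sites with columns `probe_id`,
#'   `chromosome`, `position`, and optionally `logFC_M` and `q_bh` for the
#'   summary fields.
#' @param max_gap Maximum intra-region gap in bp (default 1000).
#' @param min_cpgs Minimum region size (default 2).
#' @return Data frame of class `dmr_records`: `gene, chromosome, start, end,
#'   width, n_cpgs, member_probe_ids` (semicolon-separated), and when
#'   available `mean_logFC_M, min_q, direction`.
#' @export
group_regions <- function(sites, max_gap = 1000, min_cpgs = 2L) {
  empty <- data.frame(gene = character(), chromosome = character(),
                      start = integer(), end = integer(), width = integer(),
                      n_cpgs = integer(), member_probe_ids = character(),
                      mean_logFC_M = numeric(), min_q = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(structure(empty,
                                          class = c("dmr_records",
                                                    "data.frame")))
  out <- list()
  for (chr in unique(sites$chromosome)) {
    s <- sites[sites$chromosome == chr, , drop = FALSE]
    s <- s[order(s$position), , drop = FALSE]
    grp <- cumsum(c(1, diff(s$position) > max_gap))
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      if (nrow(m) < min_cpgs) next
      rec <- data.frame(
        gene = if ("gene" %in% names(m))
          paste(unique(m$gene), collapse = ";") else NA_character_,
        chromosome = chr,
        start = min(m$position), end = max(m$position),
        width = max(m$position) - min(m$position),
        n_cpgs = nrow(m),
        member_probe_ids = paste(m$probe_id, collapse = ";"),
        mean_logFC_M = if ("logFC_M" %in% names(m))
          mean(m$logFC_M) else NA_real_,
        min_q = if ("q_bh" %in% names(m)) min(m$q_bh) else NA_real_,
        direction = if ("logFC_M" %in% names(m)) {
          if (mean(m$logFC_M) < 0) "hypomethylated" else "hypermethylated"
        } else NA_character_,
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  structure(res, class = c("dmr_records", "data.frame"))
}

#' Detect differentially methylated regions
#'
#' Runs the full region procedure on a `dmp_result`: per chromosome, smooth
#' the squared moderated t-statistics with a truncated Gaussian kernel
#' ([kernel_smooth()]), compute moment-matched null p-values
#' ([null_pvalues()]) with BH correction across all sites, keep sites with
#' `q < fdr_threshold`, and chain them into regions ([group_regions()]).
#'
#' @param dmp_result A `dmp_result` from [identify_dmps()].
#' @param lambda,C Kernel parameters (defaults 1000 bp, 2).
#' @param fdr_threshold Site-level significance for kernel estimates
#'   (default 0.05).
#' @param max_gap,min_cpgs Region grouping parameters (defaults 1000 bp, 2).
#' @return Object of class `dmr_result`: list with `regions`
#'   (`dmr_records`), `site_table` (all sites with `S, p, q_bh`), and the
#'   parameters used.
#' @export
find_dmrs <- function(dmp_result, lambda = 1000, C = 2,
                      fdr_threshold = 0.05, max_gap = 1000, min_cpgs = 2L) {
  tab <- dmp_result$table
  tab <- tab[order(tab$chromosome, tab$position), , drop = FALSE]
  parts <- split(tab, tab$chromosome)
  sm <- do.call(rbind, lapply(parts, function(p)
    kernel_smooth(p$position, p$t, lambda = lambda, C = C)))
  tab <- do.call(rbind, parts)
  tab$S <- sm$S
  np <- null_pvalues(sm)
  tab$p_kernel <- np$p
  tab$q_kernel <- bh_adjust(np$p)
  sig <- tab[tab$q_kernel < fdr_threshold, , drop = FALSE]
  regions <- group_regions(sig, max_gap = max_gap, min_cpgs = min_cpgs)
  rownames(tab) <- NULL
  structure(list(regions = regions, site_table = tab,
                 params = list(lambda = lambda, C = C,
                               fdr_threshold = fdr_threshold,
                               max_gap = max_gap, min_cpgs = min_cpgs)),
            class = "dmr_result")
}

#' Write regions as a BED file
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention (`bed_start = start - 1`, `bed_end = end`).
#'
#' @param regions A `dmr_records` data frame.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_dmr_bed <- function(regions, path) {
  nr <- nrow(regions)
  bed <- data.frame(chrom = regions$chromosome,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = if (nr) paste0(regions$gene, "_", seq_len(nr))
                           else character(0),
                    score = rep(0L, nr), strand = rep(".", nr))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Make a run of CpG sites a plantable, recoverable region
#'
#' Adjusts positions on the run's chromosome so that (a) the run's internal
#' inter-site gaps are at most `max_internal` base pairs (a planted region
#' must be contiguous under the grouping distance) and (b) the gaps flanking
#' the run exceed `min_flank` (wider than the kernel truncation distance, so
#' smoothing cannot bleed the planted signal into neighbours). Relative
#' order of all sites is preserved. Used when planting a region whose member
#' set should be exactly recoverable.
#'
#' @param manifest A `probe_manifest`.
#' @param gene Gene name.
#' @param sites Site indices within the gene (manifest order).
#' @param min_flank Minimum flanking gap in bp (default 2500).
#' @param max_internal Maximum intra-run gap in bp (default 800).
#' @return The adjusted manifest.
#' @export
isolate_gene_run <- function(manifest, gene, sites, min_flank = 2500,
                             max_internal = 800) {
  idx <- which(manifest$probe_class == "signal" & manifest$gene == gene)
  run <- idx[sites]
  chr <- manifest$chromosome[run[1]]
  on_chr <- which(manifest$chromosome == chr)
  ord <- on_chr[order(manifest$position[on_chr])]
  pos <- manifest$position[ord]
  in_run <- ord %in% run
  gaps <- diff(pos)
  # gap i sits between sorted sites i and i+1
  internal <- which(in_run[-length(in_run)] & in_run[-1])
  gaps[internal] <- pmin(gaps[internal], max_internal)
  flank <- which(xor(in_run[-length(in_run)], in_run[-1]))
  gaps[flank] <- pmax(gaps[flank], min_flank + 1L)
  manifest$position[ord] <- as.integer(pos[1] + c(0, cumsum(gaps)))
  manifest
}
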