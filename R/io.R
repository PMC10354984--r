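# Delimited writers for the pipeline outputs. All writers are deterministic
# (fixed column order, tab separation, no quoting surprises) so that a rerun
# with the same config produces byte-identical files.

#' Write a data frame as a tab-delimited table
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a samples-x-probes matrix with a probe-id header row
#' @param m Matrix with sample rownames and probe colnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits manifest, sample sheet and the beta / detection-p / control
#' intensity matrices as delimited tables.
#'
#' @param dataset A `methylation_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(dataset$manifest), file.path(dir, "manifest.tsv"))
  write_tsv(dataset$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_matrix(dataset$beta, file.path(dir, "beta.tsv"))
  write_matrix(dataset$detection_p, file.path(dir, "detection_p.tsv"))
  write_matrix(dataset$control_intensities,
               file.path(dir, "control_intensities.tsv"))
  invisible(dir)
}

#' Read a dataset previously written by [write_dataset()]
#' @param dir Directory.
#' @return A `methylation_dataset` with `qc_state = "raw"`.
#' @export
read_dataset <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  class(man) <- c("probe_manifest", "data.frame")
  sheet <- utils::read.delim(file.path(dir, "sample_sheet.tsv"),
                             stringsAsFactors = FALSE)
  class(sheet) <- c("sample_sheet", "data.frame")
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  structure(list(beta = rd("beta.tsv"), detection_p = rd("detection_p.tsv"),
                 control_intensities = rd("control_intensities.tsv"),
                 sample_sheet = sheet, manifest = man, qc_state = "raw"),
            class = "methylation_dataset")
}
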