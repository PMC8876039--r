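#' @include AllClasses.R AllGenerics.R annotation.R
NULL

#' Read a study from wide amounts + samples TSV files
#'
#' The amounts table is species (rows) by sample ids (columns) with the
#' species names in the first column; the samples table has the fixed
#' columns \code{sample_id}, \code{genotype}, \code{treatment},
#' \code{replicate}, \code{is_qc}, \code{dry_weight_mg}, \code{run_order}.
#'
#' @param amounts_path,samples_path TSV file paths
#' @param annotate parse species names (see \code{\link{LipidStudy}})
#' @return a \linkS4class{LipidStudy}
#' @export
readStudy <- function(amounts_path, samples_path, annotate = TRUE) {
  aw <- utils::read.delim(amounts_path, check.names = FALSE)
  if (ncol(aw) < 2L)
    stop("amounts table needs a species column plus sample columns")
  m <- as.matrix(aw[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric amounts in ", amounts_path)
  rownames(m) <- aw[[1]]
  sm <- utils::read.delim(samples_path, check.names = FALSE)
  miss <- setdiff(.SAMPLE_COLUMNS, colnames(sm))
  if (length(miss))
    stop("samples table is missing column(s): ", paste(miss, collapse = ", "))
  LipidStudy(m, sm, annotate = annotate)
}

#' Read a study from a long TSV
#'
#' Long format with columns \code{sample_id}, \code{species},
#' \code{amount}; missing combinations become 0.
#'
#' @param long_path,samples_path TSV file paths
#' @param annotate parse species names
#' @export
readStudyLong <- function(long_path, samples_path, annotate = TRUE) {
  lg <- utils::read.delim(long_path, check.names = FALSE)
  need <- c("sample_id", "species", "amount")
  if (!all(need %in% colnames(lg)))
    stop("long table must have columns: ", paste(need, collapse = ", "))
  sp <- sort(unique(lg$species))
  ids <- unique(lg$sample_id)
  m <- matrix(0, length(sp), length(ids), dimnames = list(sp, ids))
  m[cbind(match(lg$species, sp), match(lg$sample_id, ids))] <- lg$amount
  sm <- utils::read.delim(samples_path, check.names = FALSE)
  LipidStudy(m, sm, annotate = annotate)
}

#' Write a study as amounts + samples TSV files
#'
#' @param study a \linkS4class{LipidStudy}
#' @param amounts_path,samples_path output paths
#' @export
writeStudy <- function(study, amounts_path, samples_path) {
  a <- amounts(study)
  out <- data.frame(species = rownames(a), a, check.names = FALSE)
  utils::write.table(out, amounts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sampleData(study)[, .SAMPLE_COLUMNS], samples_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(amounts_path, samples_path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, rowlab = "row") {
  df <- data.frame(m, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), rowlab), df)
  .write_tsv(df, path)
}
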