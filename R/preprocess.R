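#' @include AllClasses.R AllGenerics.R
NULL

#' QC-pool drift normalization
#'
#' Removes slow multiplicative instrument drift using the recurrent QC-pool
#' injections. For each analyte, the QC intensities are linearly
#' interpolated over injection run order (clamped at the run ends) and each
#' experimental intensity is divided by the interpolated QC intensity at
#' its own run position, then rescaled by the analyte's grand QC median so
#' units are preserved. QC columns themselves are passed through unchanged
#' (their raw variability feeds the CV filter). Analytes whose QC signal is
#' all zero cannot be corrected; they are passed through unchanged and
#' recorded in \code{metadata()$qc_uncorrected}.
#'
#' @param study a \linkS4class{LipidStudy} with at least two QC injections
#' @return the normalized \linkS4class{LipidStudy}
#' @export
qcNormalize <- function(study) {
  cd <- colData(study)
  nqc <- sum(cd$is_qc)
  if (nqc == 0L)
    stop("no QC samples present; to analyze unnormalized data, skip ",
         "qcNormalize() explicitly rather than calling it")
  if (nqc < 2L)
    stop("at least 2 QC injections are required for drift interpolation")
  a <- amounts(study)
  qc_idx <- which(cd$is_qc)
  exp_idx <- which(!cd$is_qc)
  qc_ord <- order(cd$run_order[qc_idx])
  qc_run <- cd$run_order[qc_idx][qc_ord]
  exp_run <- cd$run_order[exp_idx]
  flagged <- character()
  for (i in seq_len(nrow(a))) {
    qv <- a[i, qc_idx][qc_ord]
    if (all(qv == 0)) {
      flagged <- c(flagged, rownames(a)[i])
      next
    }
    ref <- stats::approx(qc_run, qv, xout = exp_run, rule = 2)$y
    ref[ref == 0] <- NA  # cannot divide where the local QC signal vanishes
    sc <- stats::median(qv) / ref
    sc[is.na(sc)] <- 1
    a[i, exp_idx] <- a[i, exp_idx] * sc
  }
  if (length(flagged))
    warning("all-zero QC signal for ", length(flagged),
            " analyte(s); passed through unnormalized")
  amounts(study) <- a
  metadata(study)$qc_normalized <- TRUE
  metadata(study)$qc_uncorrected <- flagged
  study
}

.qc_cv <- function(study) {
  q <- amounts(qcSamples(study))
  mu <- rowMeans(q)
  sdv <- apply(q, 1L, stats::sd)
  cv <- ifelse(mu == 0, Inf, sdv / mu)
  names(cv) <- rownames(q)
  cv
}

#' Remove analytes with unreliable QC measurements
#'
#' Computes each analyte's coefficient of variation over the QC-pool
#' injections (sample standard deviation, n-1 denominator, divided by the
#' mean) and removes analytes with CV strictly greater than the cutoff.
#' An analyte with zero QC mean has an undefined CV and is removed with an
#' infinite sentinel value.
#'
#' @param study a \linkS4class{LipidStudy} with >= 2 QC injections
#' @param cutoff CV threshold; the conventional value is 0.3
#' @return list with elements \code{study} (filtered) and \code{report}
#'   (a \linkS4class{FilterReport})
#' @export
filterCV <- function(study, cutoff = 0.3) {
  if (sum(isQC(study)) < 2L)
    stop("at least 2 QC injections are required to compute CVs")
  cv <- .qc_cv(study)
  drop <- names(cv)[cv > cutoff]   # strictly greater: CV == cutoff retained
  rep <- new("FilterReport", removed_lod = character(),
             removed_cv = drop, cv_values = cv)
  list(study = study[setdiff(rownames(study), drop), ], report = rep)
}

#' Remove analytes below the limit of detection
#'
#' An analyte is removed when its mean amount across experimental (non-QC)
#' samples is strictly below \code{lod}. With the default \code{lod = 0}
#' the filter is disabled.
#'
#' @param study a \linkS4class{LipidStudy} (amounts should already be per
#'   mg dry weight if the LOD is expressed in those units)
#' @param lod non-negative detection limit
#' @return list with elements \code{study} and \code{report}
#' @export
filterLOD <- function(study, lod = 0) {
  if (!is.numeric(lod) || length(lod) != 1L || lod < 0)
    stop("lod must be a single non-negative number")
  m <- rowMeans(amounts(experimentalSamples(study)))
  drop <- rownames(study)[m < lod]
  rep <- new("FilterReport", removed_lod = drop,
             removed_cv = character(), cv_values = numeric())
  list(study = study[setdiff(rownames(study), drop), ], report = rep)
}

#' Convert amounts to per-mg-dry-weight units
#'
#' Divides each experimental sample's column by that sample's dry weight in
#' mg. QC-pool columns are left untouched (they are not tissue samples).
#' Calling this twice is an error.
#'
#' @param study a \linkS4class{LipidStudy}
#' @return the converted \linkS4class{LipidStudy}
#' @export
perDryWeight <- function(study) {
  if (isTRUE(metadata(study)$per_dry_weight))
    stop("amounts are already per mg dry weight")
  cd <- colData(study)
  exp_idx <- which(!cd$is_qc)
  dw <- cd$dry_weight_mg[exp_idx]
  bad <- is.na(dw) | dw <= 0
  if (any(bad))
    stop("missing or non-positive dry weight for sample(s): ",
         paste(rownames(cd)[exp_idx][bad], collapse = ", "))
  a <- amounts(study)
  a[, exp_idx] <- sweep(a[, exp_idx, drop = FALSE], 2L, dw, "/")
  amounts(study) <- a
  metadata(study)$per_dry_weight <- TRUE
  study
}

#' Merge filter reports and write as TSV
#'
#' Writes columns \code{species}, \code{reason} (\code{"lod"} or
#' \code{"cv"}) and \code{cv_value} (empty for LOD removals).
#'
#' @param reports one \linkS4class{FilterReport} or a list of them
#' @param path output file path
#' @export
writeFilterReport <- function(reports, path) {
  if (is(reports, "FilterReport")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(r) {
    rbind(
      if (length(r@removed_lod))
        data.frame(species = r@removed_lod, reason = "lod", cv_value = NA_real_),
      if (length(r@removed_cv))
        data.frame(species = r@removed_cv, reason = "cv",
                   cv_value = unname(r@cv_values[r@removed_cv])))
  }))
  if (is.null(rows))
    rows <- data.frame(species = character(), reason = character(),
                       cv_value = numeric())
  utils::write.table(rows[order(rows$species), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
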