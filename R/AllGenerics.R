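#' @include AllClasses.R
NULL

#' Extract the lipid amount matrix
#' @param x a \linkS4class{LipidStudy}
#' @return species x samples numeric matrix
#' @export
setGeneric("amounts", function(x) standardGeneric("amounts"))

#' @rdname amounts
#' @param value replacement matrix
#' @export
setGeneric("amounts<-", function(x, value) standardGeneric("amounts<-"))

#' Sample metadata as a data.frame
#' @param x a \linkS4class{LipidStudy} or \linkS4class{TransformedStudy}
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Parsed species annotation as a data.frame
#' @param x a \linkS4class{LipidStudy}
#' @export
setGeneric("speciesData", function(x) standardGeneric("speciesData"))

setMethod("amounts", "LipidStudy", function(x) assay(x, "amounts"))
setReplaceMethod("amounts", "LipidStudy", function(x, value) {
  assay(x, "amounts") <- value
  validObject(x)
  x
})

setMethod("sampleData", "SummarizedExperiment",
          function(x) as.data.frame(colData(x)))
setMethod("speciesData", "SummarizedExperiment",
          function(x) as.data.frame(rowData(x)))

#' Logical QC flag per sample
#' @param x a \linkS4class{LipidStudy}
#' @export
isQC <- function(x) colData(x)$is_qc

#' Subset a study to its experimental (non-QC) samples
#' @param x a \linkS4class{LipidStudy}
#' @export
experimentalSamples <- function(x) x[, !isQC(x)]

#' Subset a study to its QC-pool injections
#' @param x a \linkS4class{LipidStudy}
#' @export
qcSamples <- function(x) x[, isQC(x)]

setMethod("show", "LipidStudy", function(object) {
  cd <- colData(object)
  cat("LipidStudy:", nrow(object), "species x", ncol(object), "samples (",
      sum(cd$is_qc), "QC )\n")
  if (nrow(cd) && any(!cd$is_qc)) {
    cat("  genotypes: ",
        paste(unique(as.character(cd$genotype[!cd$is_qc])), collapse = ", "),
        "\n  treatments: ",
        paste(unique(as.character(cd$treatment[!cd$is_qc])), collapse = ", "),
        "\n", sep = "")
  }
  st <- metadata(object)
  flags <- c(qc_normalized = isTRUE(st$qc_normalized),
             per_dry_weight = isTRUE(st$per_dry_weight))
  cat("  state:", paste(names(flags)[flags], collapse = ", "), "\n")
})

setMethod("show", "ModerationFit", function(object) {
  cat("ModerationFit: d0 =", format(object@d0, digits = 4),
      ", s0^2 =", format(object@s0_sq, digits = 4),
      "(", length(object@s_tilde_sq), "species )\n")
})

setMethod("show", "IonImage", function(object) {
  cat("IonImage: m/z", object@target_mz, "+/-", object@tolerance, "Da;",
      nrow(object@grid), "x", ncol(object@grid), "pixels at",
      object@pixel_size, "um; scale [",
      format(object@scale_min, digits = 4), ",",
      format(object@scale_max, digits = 4), "]\n")
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", length(object@removed_lod), "below LOD,",
      length(object@removed_cv), "QC CV > threshold\n")
})

#' Prior degrees of freedom of a moderation fit
#' @param x a \linkS4class{ModerationFit}
#' @export
priorDf <- function(x) x@d0

#' Prior variance of a moderation fit
#' @param x a \linkS4class{ModerationFit}
#' @export
priorVar <- function(x) x@s0_sq

#' Moderated (posterior) residual variances
#' @param x a \linkS4class{ModerationFit}
#' @export
moderatedVar <- function(x) x@s_tilde_sq
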