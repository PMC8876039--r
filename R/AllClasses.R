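#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData rowData<- colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Head-group classes recognised by the annotation parser
#'
#' The eleven glycerolipid head-group classes covered by the pipeline:
#' galactolipids (MGDG, DGDG), diacyl phospholipids (PG, PC, PE, PA, PS, PI)
#' and lysophospholipids (LPC, LPE, LPG).
#'
#' @export
LIPID_CLASSES <- c("MGDG", "DGDG", "PG", "PC", "PE", "PA", "PS", "PI",
                   "LPC", "LPE", "LPG")

#' Lyso (single acyl chain) head-group classes
#' @export
LYSO_CLASSES <- c("LPC", "LPE", "LPG")

.SAMPLE_COLUMNS <- c("sample_id", "genotype", "treatment", "replicate",
                     "is_qc", "dry_weight_mg", "run_order")

#' LipidStudy: a species-by-samples lipid amount matrix with sample metadata
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay
#' \code{"amounts"} holds non-negative lipid amounts (raw instrument
#' intensity before normalization, or normalized intensity per mg dry
#' weight after \code{\link{perDryWeight}}). \code{colData} carries the
#' sample sheet (genotype, treatment, replicate, QC flag, dry weight,
#' injection run order); \code{rowData} carries the parsed species
#' annotation (head class, total acyl carbons, double bonds, chain count).
#'
#' @seealso \code{\link{LipidStudy}} (constructor), \code{\link{qcNormalize}},
#'   \code{\link{transformStudy}}
#' @export
setClass("LipidStudy", contains = "SummarizedExperiment")

setValidity("LipidStudy", function(object) {
  msg <- character()
  if (!"amounts" %in% names(assays(object)))
    msg <- c(msg, "assay 'amounts' is required")
  else {
    a <- assay(object, "amounts")
    if (any(!is.finite(a)))
      msg <- c(msg, "amounts must be finite")
    else if (any(a < 0))
      msg <- c(msg, "amounts must be non-negative (zeros mark below-detection)")
  }
  cd <- colData(object)
  need <- setdiff(.SAMPLE_COLUMNS, c("sample_id", colnames(cd)))
  if (length(need))
    msg <- c(msg, paste0("missing sample metadata columns: ",
                         paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(cd$run_order))
      msg <- c(msg, "run_order values must be unique")
    exp <- !cd$is_qc
    if (any(exp & (is.na(cd$genotype) | is.na(cd$treatment))))
      msg <- c(msg, "every non-QC sample needs genotype and treatment")
    dw <- cd$dry_weight_mg[exp]
    if (any(!is.na(dw) & dw <= 0))
      msg <- c(msg, "dry_weight_mg must be positive for experimental samples")
  }
  if (length(msg)) msg else TRUE
})

#' TransformedStudy: log2 upper-quartile transformed values with weights
#'
#' Extends \linkS4class{SummarizedExperiment} with assays \code{"y"}
#' (transformed values \eqn{y_{ij} = \log_2((r_{ij}+\delta)/R_j \times 10^6)})
#' and \code{"w"} (strictly positive per-observation precision weights,
#' unit until \code{\link{voomWeights}} is applied). The pseudo-amount
#' \eqn{\delta} is stored in \code{metadata()$delta} and the per-sample
#' upper quartiles \eqn{R_j} in \code{colData()$upper_quartile}.
#'
#' @export
setClass("TransformedStudy", contains = "SummarizedExperiment")

setValidity("TransformedStudy", function(object) {
  msg <- character()
  if (!all(c("y", "w") %in% names(assays(object))))
    msg <- c(msg, "assays 'y' and 'w' are required")
  else {
    if (any(!is.finite(assay(object, "y"))))
      msg <- c(msg, "transformed values must be finite")
    if (any(assay(object, "w") <= 0))
      msg <- c(msg, "precision weights must be strictly positive")
  }
  if (is.null(metadata(object)$delta) || metadata(object)$delta <= 0)
    msg <- c(msg, "metadata()$delta must be a positive pseudo-amount")
  if (length(msg)) msg else TRUE
})

#' Per-species weighted linear model fits on the transformed scale
#'
#' Cell-means fits of each lipid's transformed values on the
#' genotype-by-treatment design. \code{coefficients} are cell means
#' (species x cells); \code{cov_unscaled} holds per-species
#' \eqn{(X'WX)^{-1}} so arbitrary cell contrasts can be tested.
#'
#' @slot coefficients species x cells matrix of cell means
#' @slot cov_unscaled cells x cells x species array of unscaled covariances
#' @slot sigma_sq per-species residual variance
#' @slot df_residual per-species residual degrees of freedom
#' @slot cells data.frame mapping cell label to genotype and treatment
#' @export
setClass("LipidFit", representation(
  coefficients = "matrix",
  cov_unscaled = "array",
  sigma_sq     = "numeric",
  df_residual  = "numeric",
  cells        = "data.frame"))

#' Empirical-Bayes variance moderation fit
#'
#' Hyperparameters of the scaled inverse-chi-square prior on residual
#' variances, estimated by matching moments of log residual variances,
#' together with the per-species moderated (posterior) variances.
#'
#' @slot d0 prior degrees of freedom (may be \code{Inf})
#' @slot s0_sq prior variance
#' @slot s_tilde_sq per-species moderated residual variance
#' @slot df_residual per-species residual df of the underlying fits
#' @export
setClass("ModerationFit", representation(
  d0          = "numeric",
  s0_sq       = "numeric",
  s_tilde_sq  = "numeric",
  df_residual = "numeric"))

setValidity("ModerationFit", function(object) {
  msg <- character()
  if (length(object@d0) != 1L || object@d0 < 0)
    msg <- c(msg, "d0 must be a single value >= 0 (Inf allowed)")
  if (length(object@s0_sq) != 1L || object@s0_sq <= 0)
    msg <- c(msg, "s0_sq must be a single positive value")
  lo <- pmin(object@s0_sq, pmin(object@s_tilde_sq, Inf))
  if (length(object@s_tilde_sq) != length(object@df_residual))
    msg <- c(msg, "s_tilde_sq and df_residual lengths differ")
  if (length(msg)) msg else TRUE
})

#' Report of analytes removed by LOD and QC-CV filters
#'
#' @slot removed_lod species removed because their mean per-dry-weight
#'   amount fell below the limit of detection
#' @slot removed_cv species removed because their QC coefficient of
#'   variation exceeded 0.3 (or was undefined)
#' @slot cv_values named per-species QC coefficients of variation
#' @export
setClass("FilterReport", representation(
  removed_lod = "character",
  removed_cv  = "character",
  cv_values   = "numeric"))

#' Principal component analysis of the lipidome
#'
#' @slot scores samples x components score matrix
#' @slot loadings species x components loading matrix
#' @slot var_explained fraction of variance per component (sums to 1)
#' @export
setClass("PcaResult", representation(
  scores        = "matrix",
  loadings      = "matrix",
  var_explained = "numeric"))

setValidity("PcaResult", function(object) {
  v <- object@var_explained
  if (any(diff(v) > 1e-8))
    return("component variances must be non-increasing")
  if (abs(sum(v) - 1) > 1e-6)
    return("var_explained must sum to 1")
  TRUE
})

#' Rectangular ion image for one target m/z
#'
#' Intensities summed within a closed mass window
#' \eqn{|m/z - target| \le tolerance} at each raster pixel. Display scale
#' bounds may span several images after \code{\link{commonScale}}.
#'
#' @slot grid x-by-y intensity matrix (absent pixels are 0)
#' @slot target_mz target m/z in Da
#' @slot tolerance half-width of the mass window in Da
#' @slot scale_min,scale_max display scale bounds
#' @slot pixel_size raster pitch in micrometres
#' @export
setClass("IonImage", representation(
  grid       = "matrix",
  target_mz  = "numeric",
  tolerance  = "numeric",
  scale_min  = "numeric",
  scale_max  = "numeric",
  pixel_size = "numeric"))

setValidity("IonImage", function(object) {
  msg <- character()
  if (any(object@grid < 0)) msg <- c(msg, "grid intensities must be non-negative")
  if (object@scale_min > object@scale_max)
    msg <- c(msg, "scale_min must not exceed scale_max")
  if (object@tolerance <= 0) msg <- c(msg, "tolerance must be positive")
  if (length(msg)) msg else TRUE
})
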