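#' @include AllClasses.R AllGenerics.R
NULL

#' Principal component analysis of the lipidome
#'
#' Amounts are log10-transformed with the same global pseudo-amount rule
#' used by the log2 analysis transform (half the smallest non-zero amount,
#' which keeps below-detection zeros finite), samples are treated as
#' observations and species as variables, columns are centered, and the
#' covariance matrix is eigendecomposed (no unit-variance scaling). QC
#' injections are excluded.
#'
#' @param study a \linkS4class{LipidStudy} with >= 2 samples and species
#' @return a \linkS4class{PcaResult}; \code{varExplained} gives percentages
#' @export
lipidPCA <- function(study) {
  es <- experimentalSamples(study)
  a <- amounts(es)
  if (nrow(a) < 2L || ncol(a) < 2L)
    stop("need at least 2 species and 2 samples")
  pos <- a[a > 0]
  delta <- if (length(pos)) min(pos) / 2 else 1
  x <- t(log10(a + delta))       # samples as observations
  if (all(apply(x, 2L, stats::var) < .Machine$double.eps))
    stop("constant matrix: no variance to decompose")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  new("PcaResult", scores = pr$x, loadings = pr$rotation,
      var_explained = v / sum(v))
}

#' Per-component variance explained, in percent
#' @param x a \linkS4class{PcaResult}
#' @export
varExplained <- function(x) 100 * x@var_explained

#' Sample scores of a PCA
#' @param x a \linkS4class{PcaResult}
#' @export
pcaScores <- function(x) x@scores

#' Hierarchical-clustering leaf order for heat maps
#'
#' Euclidean distance, complete linkage; returns the dendrogram leaf order
#' used to arrange heat-map rows or columns.
#'
#' @param m numeric matrix
#' @param axis cluster \code{"rows"} or \code{"cols"}
#' @param method linkage passed to \code{\link[stats]{hclust}}
#' @return integer permutation of row (or column) indices
#' @export
hclustOrder <- function(m, axis = c("rows", "cols"), method = "complete") {
  axis <- match.arg(axis)
  if (axis == "cols") m <- t(m)
  if (any(!is.finite(m)))
    stop("matrix contains non-finite entries; impute or mask before clustering")
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  stats::hclust(stats::dist(m, method = "euclidean"), method = method)$order
}
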