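#' @include AllClasses.R AllGenerics.R
NULL

#' Upper-quartile log2 transformation
#'
#' Transforms per-sample lipid amounts \eqn{r_{ij}} to
#' \deqn{y_{ij} = \log_2\!\left(\frac{r_{ij} + \delta}{R_j} \times 10^6\right)}
#' where \eqn{\delta} is half the smallest non-zero amount over the whole
#' experimental matrix (one global pseudo-amount, which keeps zeros finite)
#' and \eqn{R_j} is the upper quartile (75th percentile, linear-interpolation
#' quantile) of sample \eqn{j}'s non-zero amounts. QC injections are
#' excluded; they serve preprocessing only. The result is invariant to a
#' global rescaling of the amounts matrix and strictly increasing in
#' \eqn{r_{ij}} within a sample.
#'
#' Precision weights are initialised to 1; apply \code{\link{voomWeights}}
#' to estimate mean-variance trend weights.
#'
#' @param study a \linkS4class{LipidStudy} with at least one positive amount
#' @return a \linkS4class{TransformedStudy}
#' @export
transformStudy <- function(study) {
  es <- experimentalSamples(study)
  a <- amounts(es)
  pos <- a[a > 0]
  if (!length(pos))
    stop("no positive amounts in the experimental matrix")
  delta <- min(pos) / 2
  allzero <- colSums(a > 0) == 0L
  if (any(allzero))
    stop("sample(s) with all-zero amounts: ",
         paste(colnames(a)[allzero], collapse = ", "))
  Rj <- apply(a, 2L, function(x) stats::quantile(x[x > 0], 0.75,
                                                 names = FALSE, type = 7))
  y <- log2(sweep(a + delta, 2L, Rj, "/") * 1e6)
  cd <- colData(es)
  cd$upper_quartile <- Rj
  se <- SummarizedExperiment(
    assays = list(y = y, w = matrix(1, nrow(y), ncol(y),
                                    dimnames = dimnames(y))),
    colData = cd, rowData = rowData(es),
    metadata = list(delta = delta))
  new("TransformedStudy", se)
}

.design_cells <- function(cd) {
  g <- as.character(cd$genotype)
  t <- as.character(cd$treatment)
  combos <- expand.grid(genotype = unique(g), treatment = unique(t),
                        stringsAsFactors = FALSE)
  combos$cell <- paste(combos$genotype, combos$treatment, sep = " | ")
  cell <- paste(g, t, sep = " | ")
  n <- table(factor(cell, levels = combos$cell))
  empty <- names(n)[n == 0L]
  if (length(empty))
    stop("empty genotype x treatment cell(s): ", paste(empty, collapse = ", "))
  X <- stats::model.matrix(~ 0 + factor(cell, levels = combos$cell))
  colnames(X) <- combos$cell
  list(X = X, cells = combos)
}

#' Mean-variance trend precision weights
#'
#' Estimates observation-level precision weights from the mean-variance
#' relationship of the transformed data. Each species' unweighted linear
#' model on the genotype-by-treatment cell-means design is fitted; the
#' square root of the residual standard deviation is regressed on the mean
#' transformed value with a locally weighted smoother (\code{lowess},
#' default span 0.5); the fitted trend, evaluated at each observation's
#' fitted value, predicts that observation's standard deviation, and the
#' weight is the predicted SD to the power -4 (inverse predicted variance
#' squared through the sqrt-SD parameterisation). Weights are clipped to
#' \code{clip}. With fewer than 10 species the trend is unreliable and unit
#' weights are returned with a warning.
#'
#' @param ts a \linkS4class{TransformedStudy}
#' @param span lowess span as a fraction of points
#' @param clip length-2 positive range to which weights are clipped
#' @return \code{ts} with its \code{"w"} assay replaced
#' @export
voomWeights <- function(ts, span = 0.5, clip = c(1e-4, 1e4)) {
  y <- assay(ts, "y")
  if (nrow(y) < 10L) {
    warning("fewer than 10 species: mean-variance trend unreliable, ",
            "using unit weights")
    assay(ts, "w") <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
    return(ts)
  }
  d <- .design_cells(colData(ts))
  qrX <- qr(d$X)
  df <- ncol(y) - qrX$rank
  if (df < 2L)
    stop("fewer than 2 residual degrees of freedom; cannot estimate a trend")
  fitted <- t(qr.fitted(qrX, t(y)))
  res <- y - fitted
  s <- sqrt(rowSums(res^2) / df)
  mean_y <- rowMeans(y)
  lo <- stats::lowess(mean_y, sqrt(s), f = span)
  pred <- stats::approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2,
                        ties = mean)$y
  pred <- pmax(pred, 1e-8)
  w <- matrix(pred^(-4), nrow(y), ncol(y), dimnames = dimnames(y))
  w <- pmin(pmax(w, clip[1]), clip[2])
  assay(ts, "w") <- w
  ts
}
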