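#' @include AllClasses.R AllGenerics.R transform.R
NULL

#' Per-species weighted least-squares fits
#'
#' Fits each species' transformed values on the genotype-by-treatment
#' cell-means design by weighted least squares using the precision weights
#' of \code{ts}. Any declared genotype x treatment cell without samples
#' makes the design rank-deficient and is reported by name.
#'
#' @param ts a \linkS4class{TransformedStudy}
#' @return a \linkS4class{LipidFit}
#' @export
fitCellMeans <- function(ts) {
  y <- assay(ts, "y")
  w <- assay(ts, "w")
  d <- .design_cells(colData(ts))
  X <- d$X
  p <- ncol(X)
  n <- ncol(y)
  if (n <= p)
    stop("no residual degrees of freedom: ", n, " samples for ", p, " cells")
  nsp <- nrow(y)
  coefs <- matrix(NA_real_, nsp, p, dimnames = list(rownames(y), colnames(X)))
  covu <- array(NA_real_, c(p, p, nsp),
                dimnames = list(colnames(X), colnames(X), rownames(y)))
  s2 <- numeric(nsp)
  for (i in seq_len(nsp)) {
    wi <- w[i, ]
    sw <- sqrt(wi)
    Xw <- X * sw
    XtX <- crossprod(Xw)
    XtXi <- chol2inv(chol(XtX))
    b <- XtXi %*% crossprod(Xw, y[i, ] * sw)
    r <- y[i, ] - X %*% b
    coefs[i, ] <- b
    covu[, , i] <- XtXi
    s2[i] <- sum(wi * r^2) / (n - p)
  }
  names(s2) <- rownames(y)
  new("LipidFit", coefficients = coefs, cov_unscaled = covu,
      sigma_sq = s2, df_residual = rep(n - p, nsp), cells = d$cells)
}

#' Invert the trigamma function
#'
#' Newton iteration on the strictly decreasing trigamma function; used to
#' match the variance of log residual variances to its theoretical value
#' under the scaled inverse-chi-square prior.
#'
#' @param x positive values
#' @return y such that \code{trigamma(y) = x}
#' @export
trigammaInverse <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  y <- 0.5 + 1 / x
  for (iter in 1:100) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(-dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Assumes the per-species residual variances \eqn{s_g^2} are draws from a
#' scaled inverse-chi-square prior with hyperparameters \eqn{(d_0, s_0^2)},
#' so that \eqn{s_g^2 \sim s_0^2 F_{d_g, d_0}}. The hyperparameters are
#' estimated by matching the first two moments of \eqn{\log s_g^2} to their
#' theoretical values (digamma/trigamma identities; the trigamma equation
#' is inverted by Newton iteration). The moderated variance is the
#' posterior mean
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' a convex combination of the observed and prior variances. When the
#' observed log-variances are underdispersed relative to pure chi-square
#' sampling noise, \eqn{d_0 = \infty} and all moderated variances equal
#' \eqn{s_0^2}.
#'
#' @param fit a \linkS4class{LipidFit}, or a numeric vector of residual
#'   variances (then \code{df} must be given)
#' @param df residual degrees of freedom (scalar or per-species)
#' @return a \linkS4class{ModerationFit}
#' @export
moderateVariances <- function(fit, df = NULL) {
  if (is(fit, "LipidFit")) {
    s2 <- fit@sigma_sq
    d <- fit@df_residual
  } else {
    s2 <- fit
    if (is.null(df)) stop("df is required when passing raw variances")
    d <- rep_len(df, length(s2))
  }
  if (sum(d > 0) < 2L)
    stop("need at least 2 species with positive residual df")
  ok <- d > 0 & s2 > 0
  if (sum(ok) < 2L)
    stop("need at least 2 positive residual variances to estimate the prior")
  e <- log(s2[ok]) - digamma(d[ok] / 2) + log(d[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    t0 <- trigammaInverse(evar)
    d0 <- 2 * t0
    s0_sq <- exp(emean + digamma(t0) - log(t0))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  st <- if (is.infinite(d0)) rep_len(s0_sq, length(s2))
        else (d0 * s0_sq + d * s2) / (d0 + d)
  names(st) <- names(s2)
  new("ModerationFit", d0 = d0, s0_sq = s0_sq, s_tilde_sq = st,
      df_residual = d)
}

#' Storey q-values
#'
#' Converts p-values to q-values with the proportion of true nulls
#' \eqn{\pi_0} estimated by the smoother method: \eqn{\pi_0(\lambda)} is
#' computed over the grid \eqn{\lambda = 0.05, 0.10, \ldots, 0.95}, a
#' natural cubic smoothing spline (3 df) is fitted, and the fit is
#' evaluated at the largest \eqn{\lambda}. With fewer than 100 p-values, or
#' when the estimate leaves \eqn{(0, 1]}, the conservative fallback
#' \eqn{\pi_0 = 1} is used, in which case the q-values equal
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @param pi0 optionally force a null proportion (e.g. \code{pi0 = 1})
#' @return q-values in the order of \code{p}
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (!length(p)) return(numeric())
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      est <- stats::predict(sp, x = max(lambda))$y
      pi0 <- if (!is.finite(est) || est <= 0 || est > 1) 1 else est
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))[ro]
  q
}

#' Differential tests for the three contrast families
#'
#' Emits per-species moderated-t results for
#' \enumerate{
#'   \item genotype vs reference (WT) within each treatment,
#'   \item treatment effect (second vs first treatment level) within each
#'     genotype,
#'   \item genotype-by-treatment interaction (difference of the treatment
#'     effects between genotype and reference).
#' }
#' Effects are differences of cell means on the transformed (log2) scale.
#' Moderated t-statistics use the moderated variance with
#' \eqn{d_0 + d_g} degrees of freedom. q-values are computed within each
#' contrast family, and \code{significant} flags \code{q <= q_threshold}.
#' Rows are ordered species-alphabetically then by contrast for
#' reproducible output.
#'
#' @param fit a \linkS4class{LipidFit}
#' @param mf the matching \linkS4class{ModerationFit}
#' @param q_threshold significance threshold on q-values (default 0.1)
#' @param reference reference genotype (default \code{"WT"} when present)
#' @param pi0 optional forced null proportion passed to \code{\link{qvalues}}
#' @return data.frame with columns \code{species}, \code{contrast_family},
#'   \code{contrast}, \code{log2_fc}, \code{stat}, \code{p_value},
#'   \code{q_value}, \code{significant}
#' @export
runContrasts <- function(fit, mf, q_threshold = 0.1, reference = NULL,
                         pi0 = NULL) {
  cells <- fit@cells
  genos <- unique(cells$genotype)
  trts <- unique(cells$treatment)
  if (is.null(reference))
    reference <- if ("WT" %in% genos) "WT" else genos[1]
  if (!reference %in% genos)
    stop("reference genotype ", sQuote(reference), " not in design")
  ccol <- function(g, t) which(cells$genotype == g & cells$treatment == t)

  contr <- list()
  for (t in trts)
    for (g in setdiff(genos, reference)) {
      v <- numeric(nrow(cells))
      v[ccol(g, t)] <- 1; v[ccol(reference, t)] <- -1
      contr[[length(contr) + 1L]] <- list(
        family = "genotype_within_treatment",
        id = sprintf("%s vs %s (%s)", g, reference, t), v = v)
    }
  if (length(trts) >= 2L) {
    tA <- trts[1]; tB <- trts[2]
    for (g in genos) {
      v <- numeric(nrow(cells))
      v[ccol(g, tB)] <- 1; v[ccol(g, tA)] <- -1
      contr[[length(contr) + 1L]] <- list(
        family = "treatment_within_genotype",
        id = sprintf("%s vs %s (%s)", tB, tA, g), v = v)
    }
    for (g in setdiff(genos, reference)) {
      v <- numeric(nrow(cells))
      v[ccol(g, tB)] <- 1; v[ccol(g, tA)] <- -1
      v[ccol(reference, tB)] <- v[ccol(reference, tB)] - 1
      v[ccol(reference, tA)] <- v[ccol(reference, tA)] + 1
      contr[[length(contr) + 1L]] <- list(
        family = "interaction",
        id = sprintf("(%s vs %s) x (%s vs %s)", g, reference, tB, tA), v = v)
    }
  }

  species <- rownames(fit@coefficients)
  nsp <- length(species)
  # total df capped at the pooled residual df: the prior cannot carry more
  # information than the ensemble of per-species variances it was fit to
  df_total <- pmin(mf@d0 + mf@df_residual, sum(mf@df_residual))
  out <- do.call(rbind, lapply(contr, function(cn) {
    est <- as.vector(fit@coefficients %*% cn$v)
    vu <- vapply(seq_len(nsp),
                 function(i) drop(t(cn$v) %*% fit@cov_unscaled[, , i] %*% cn$v),
                 0)
    se <- sqrt(mf@s_tilde_sq * vu)
    tt <- est / se
    pv <- 2 * stats::pt(-abs(tt), df = df_total)
    data.frame(species = species, contrast_family = cn$family,
               contrast = cn$id, log2_fc = est, stat = tt, p_value = pv,
               stringsAsFactors = FALSE)
  }))
  out$q_value <- NA_real_
  for (fam in unique(out$contrast_family)) {
    sel <- out$contrast_family == fam
    out$q_value[sel] <- qvalues(out$p_value[sel], pi0 = pi0)
  }
  out$significant <- out$q_value <= q_threshold
  out[order(out$species, out$contrast_family, out$contrast), ]
}

#' All-pairwise genotype tests within one treatment
#'
#' Moderated t-tests for every genotype pair within the given treatment,
#' with q-values over the whole set. The significance matrix feeds
#' \code{\link{compactLetters}}.
#'
#' @inheritParams runContrasts
#' @param species which species (row of the fit) to test
#' @param treatment treatment level
#' @return list with the pairwise results data.frame and, per species, a
#'   symmetric logical significance matrix
#' @export
pairwiseGenotypeTests <- function(fit, mf, treatment, species = NULL,
                                  q_threshold = 0.1) {
  cells <- fit@cells
  genos <- unique(cells$genotype[cells$treatment == treatment])
  if (length(genos) < 2L) stop("need >= 2 genotypes")
  if (is.null(species)) species <- rownames(fit@coefficients)
  pairs <- utils::combn(genos, 2L)
  df_total <- pmin(mf@d0 + mf@df_residual, sum(mf@df_residual))
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    v <- numeric(nrow(cells))
    v[cells$genotype == g1 & cells$treatment == treatment] <- 1
    v[cells$genotype == g2 & cells$treatment == treatment] <- -1
    idx <- match(species, rownames(fit@coefficients))
    est <- as.vector(fit@coefficients[idx, , drop = FALSE] %*% v)
    vu <- vapply(idx, function(i) drop(t(v) %*% fit@cov_unscaled[, , i] %*% v), 0)
    tt <- est / sqrt(mf@s_tilde_sq[idx] * vu)
    pv <- 2 * stats::pt(-abs(tt), df = df_total[idx])
    rows[[k]] <- data.frame(species = species, g1 = g1, g2 = g2,
                            log2_fc = est, stat = tt, p_value = pv,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q_value <- qvalues(res$p_value)
  res$significant <- res$q_value <= q_threshold
  mats <- lapply(species, function(sp) {
    m <- matrix(FALSE, length(genos), length(genos),
                dimnames = list(genos, genos))
    sub <- res[res$species == sp, ]
    for (r in seq_len(nrow(sub)))
      m[sub$g1[r], sub$g2[r]] <- m[sub$g2[r], sub$g1[r]] <- sub$significant[r]
    m
  })
  names(mats) <- species
  list(results = res, significance = mats)
}

#' Compact letter display
#'
#' Encodes a symmetric pairwise-significance matrix as letter sets by the
#' insert-and-absorb algorithm: groups that are not significantly different
#' share at least one letter; significantly different pairs share none.
#'
#' @param signif symmetric logical matrix (TRUE = significantly different)
#'   with group names as dimnames
#' @return named character vector of letter strings per group
#' @export
compactLetters <- function(signif) {
  stopifnot(is.matrix(signif), nrow(signif) == ncol(signif))
  if (!isTRUE(all.equal(signif, t(signif))))
    stop("significance matrix must be symmetric")
  groups <- rownames(signif)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(signif)))
  cols <- list(groups)
  idx <- which(upper.tri(signif) & signif, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    gi <- groups[idx[k, 1]]; gj <- groups[idx[k, 2]]
    newcols <- list()
    for (col in cols) {
      if (gi %in% col && gj %in% col)
        newcols <- c(newcols, list(setdiff(col, gi), setdiff(col, gj)))
      else
        newcols <- c(newcols, list(col))
    }
    # absorb: drop any column whose members are a subset of another's
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols))
      for (b in seq_along(newcols))
        if (a != b && keep[a] &&
            all(newcols[[a]] %in% newcols[[b]]) &&
            (length(newcols[[a]]) < length(newcols[[b]]) || a > b))
          keep[a] <- FALSE
    cols <- newcols[keep]
  }
  # order letter columns by their earliest member so the first group gets "a"
  cols <- cols[order(vapply(cols, function(col) min(match(col, groups)), 1L))]
  labs <- vapply(groups, function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, TRUE))],
          collapse = "")
  }, "")
  labs
}
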