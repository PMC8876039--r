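fitToy <- function(y_rows, groups = rep(c("WT", "mut"), each = 3),
                   weights = NULL) {
  # build a TransformedStudy-like fit directly from given transformed rows
  y <- do.call(rbind, y_rows)
  rownames(y) <- sprintf("PC %d:1", 30 + 2 * seq_len(nrow(y)))
  colnames(y) <- sprintf("s%02d", seq_len(ncol(y)))
  if (is.null(weights)) weights <- matrix(1, nrow(y), ncol(y))
  cd <- sampleSheet(ncol(y), genotype = groups)
  cd$sample_id <- colnames(y)
  se <- SummarizedExperiment(assays = list(y = y, w = weights),
                             colData = cd, metadata = list(delta = 1))
  fitCellMeans(new("TransformedStudy", se))
}

test_that("two-group cell means reproduce textbook least squares", {
  fit <- fitToy(list(c(1, 2, 3, 4, 5, 6)))
  expect_equal(unname(fit@coefficients[1, ]), c(2, 5))
  expect_equal(unname(fit@sigma_sq[1]), 1)
  expect_equal(unname(fit@df_residual[1]), 4)
  # contrast variance: 1/3 + 1/3
  v <- c(-1, 1)
  expect_equal(drop(t(v) %*% fit@cov_unscaled[, , 1] %*% v), 2 / 3)
})

test_that("coefficients are invariant to uniform weight rescaling", {
  y <- list(c(1.2, 0.7, 2.3, 4.1, 3.3, 5.0))
  f1 <- fitToy(y)
  f2 <- fitToy(y, weights = matrix(2, 1, 6))
  expect_equal(f1@coefficients, f2@coefficients)
})

test_that("exact-fit data gives zero residual variance", {
  fit <- fitToy(list(c(1, 1, 1, 2, 2, 2)))
  expect_equal(unname(fit@sigma_sq[1]), 0)
})

test_that("an empty genotype x treatment cell is reported by name", {
  a <- matrix(rlnorm(40), 10, 4)
  sm <- sampleSheet(4, genotype = c("WT", "WT", "mut", "mut"),
                    treatment = c("+N", "-N", "+N", "+N"))
  st <- toyStudy(a, sm)
  expect_error(fitCellMeans(transformStudy(st)), "mut | -N", fixed = TRUE)
})

test_that("equal residual variances trigger the infinite-prior branch", {
  mf <- moderateVariances(rep(2.5, 50), df = 4)
  expect_equal(priorDf(mf), Inf)
  expect_equal(moderatedVar(mf), rep(priorVar(mf), 50))
  # and in that limit the moderated variance is the common variance scale
  expect_equal(priorVar(mf), exp(mean(log(2.5)) - digamma(2) + log(2)),
               tolerance = 1e-12)
})

test_that("moderated variances are convex combinations of s_g^2 and s0^2", {
  set.seed(1)
  s2 <- 2 * rf(500, 6, 5)
  mf <- moderateVariances(s2, df = 6)
  st <- moderatedVar(mf)
  expect_true(all(st >= pmin(s2, priorVar(mf)) - 1e-12))
  expect_true(all(st <= pmax(s2, priorVar(mf)) + 1e-12))
  expect_equal(st, (priorDf(mf) * priorVar(mf) + 6 * s2) / (priorDf(mf) + 6))
})

test_that("hyperparameter estimates agree with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(21)
  s2 <- 1.7 * rf(800, 8, 5)
  mf <- moderateVariances(s2, df = 8)
  sq <- limma::squeezeVar(s2, df = 8)
  expect_equal(priorDf(mf), sq$df.prior, tolerance = 1e-6)
  expect_equal(priorVar(mf), sq$var.prior, tolerance = 1e-6)
  expect_equal(unname(moderatedVar(mf)), sq$var.post, tolerance = 1e-6)
})

test_that("moderated t-statistics agree with the reference pipeline", {
  skip_if_not_installed("limma")
  set.seed(31)
  n <- 150
  y <- matrix(rnorm(n * 6, mean = 8), n, 6,
              dimnames = list(sprintf("PC %d:2", 30 + seq_len(n)),
                              sprintf("s%02d", 1:6)))
  w <- matrix(runif(n * 6, 0.5, 2), n, 6, dimnames = dimnames(y))
  cd <- sampleSheet(6, genotype = rep(c("WT", "mut"), each = 3))
  se <- SummarizedExperiment(assays = list(y = y, w = w), colData = cd,
                             metadata = list(delta = 1))
  fit <- fitCellMeans(new("TransformedStudy", se))
  mf <- moderateVariances(fit)
  res <- runContrasts(fit, mf, pi0 = 1)

  design <- model.matrix(~ rep(c(0, 1), each = 3))
  lf <- limma::eBayes(limma::lmFit(y, design, weights = w))
  expect_equal(unname(res$log2_fc[match(rownames(y), res$species)]),
               unname(lf$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(unname(res$stat[match(rownames(y), res$species)]),
               unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(res$p_value[match(rownames(y), res$species)]),
               unname(lf$p.value[, 2]), tolerance = 1e-5)
})

test_that("q-values equal Benjamini-Hochberg when pi0 is 1", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(qvalues(p, pi0 = 1), c(0.03, 0.03, 0.03))
  set.seed(9)
  p <- runif(50)^2
  expect_equal(qvalues(p, pi0 = 1), p.adjust(p, "BH"))
  # brute-force direct formula on a small vector
  p <- c(0.40, 0.01, 0.55, 0.13, 0.13, 0.90, 0.02)
  m <- length(p)
  brute <- vapply(seq_len(m), function(i) {
    min(vapply(which(p >= p[i] - 1e-15), function(j)
      m * p[j] / sum(p <= p[j] + 1e-15), 0), 1)
  }, 0)
  expect_equal(qvalues(p, pi0 = 1), brute)
})

test_that("q-values are monotone, bounded and near-null-calibrated", {
  expect_identical(qvalues(numeric()), numeric())
  expect_equal(qvalues(rep(1, 20)), rep(1, 20))
  set.seed(77)
  p <- runif(2000)
  q <- qvalues(p)
  expect_true(all(q <= 1 & q >= 0))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # uniform nulls: fraction called at q <= 0.05 stays near or below the level
  expect_lte(mean(q <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("identical groups give exactly zero effect estimates", {
  set.seed(3)
  half <- matrix(rlnorm(30, 2, 0.6), 10, 3)
  st <- twoGroupStudy(cbind(half, half), 3)   # mut duplicates WT exactly
  fit <- fitCellMeans(transformStudy(st))
  mf <- moderateVariances(fit)
  res <- runContrasts(fit, mf)
  expect_equal(res$log2_fc, rep(0, 10))
})

test_that("compact letters encode exactly the non-significance relation", {
  no_diff <- matrix(FALSE, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_equal(unname(compactLetters(no_diff)), c("a", "a", "a"))

  all_diff <- !diag(3) > 0
  dimnames(all_diff) <- list(LETTERS[1:3], LETTERS[1:3])
  expect_equal(unname(compactLetters(all_diff)), c("a", "b", "c"))

  chain <- matrix(FALSE, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  chain["A", "C"] <- chain["C", "A"] <- TRUE
  expect_equal(compactLetters(chain), c(A = "a", B = "ab", C = "b"))

  expect_error(compactLetters(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)),
               "symmetric")

  # exhaustive decode-equivalence for up to 5 groups
  for (n in 2:5) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (code in seq_len(2^nrow(pairs)) - 1L) {
      m <- matrix(FALSE, n, n, dimnames = list(letters[1:n], letters[1:n]))
      bits <- bitwAnd(bitwShiftR(code, seq_len(nrow(pairs)) - 1L), 1L) == 1L
      m[pairs[bits, , drop = FALSE]] <- TRUE
      m <- m | t(m)
      lab <- compactLetters(m)
      share <- outer(lab, lab, Vectorize(function(x, y)
        length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0))
      decoded <- !share
      diag(decoded) <- FALSE
      expect_equal(unname(decoded), unname(m))
      if (any(decoded != m)) break
    }
  }
})
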