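#' @include AllClasses.R AllGenerics.R
NULL

.check_annotated <- function(study) {
  rd <- speciesData(study)
  if (!"head_class" %in% colnames(rd) || anyNA(rd$head_class))
    stop("unannotated species present; construct the study with annotate = TRUE")
  rd
}

#' Head-group class totals, total lipid and composition fractions
#'
#' Per-sample sums of amounts by head-group class, the grand total over all
#' measured species ("total lipid"), and the per-class mol fractions
#' (class total divided by total lipid). Lyso classes are included in the
#' total. Experimental (non-QC) samples only.
#'
#' @param study an annotated \linkS4class{LipidStudy}
#' @return list with \code{class_totals} (class x samples), \code{total_lipid}
#'   (per sample), \code{mol_fraction} (class x samples)
#' @export
classTotals <- function(study) {
  rd <- .check_annotated(study)
  a <- amounts(experimentalSamples(study))
  ct <- rowsum(a, group = rd$head_class)
  tot <- colSums(ct)
  frac <- sweep(ct, 2L, tot, "/")
  list(class_totals = ct, total_lipid = tot, mol_fraction = frac)
}

#' Chain-length / double-bond group sums
#'
#' For every observed \code{"C:D"} key, the per-sample sum of all species
#' from all head-group classes sharing that total chain length and number
#' of double bonds (e.g. the 36:6, 38:4, 38:5, 38:6, 42:2, 42:3 groups).
#' Keys with no species are absent rather than zero rows.
#'
#' @param study an annotated \linkS4class{LipidStudy}
#' @return group x samples matrix, rows named by key
#' @export
groupSums <- function(study) {
  rd <- .check_annotated(study)
  a <- amounts(experimentalSamples(study))
  gs <- rowsum(a, group = groupKey(rd))
  # order by carbons then double bonds
  key <- do.call(rbind, strsplit(rownames(gs), ":", fixed = TRUE))
  gs[order(as.integer(key[, 1]), as.integer(key[, 2])), , drop = FALSE]
}

#' Unsaturation indices
#'
#' The unsaturation index of a species is its amount multiplied by its
#' average number of double bonds per acyl chain (total double bonds /
#' number of chains). The index of a head-group class is the sum of its
#' species' indices, per sample. Indices scale linearly with amounts.
#'
#' @param study an annotated \linkS4class{LipidStudy}
#' @return list with \code{species_index} (species x samples) and
#'   \code{class_index} (class x samples)
#' @export
unsaturationIndex <- function(study) {
  rd <- .check_annotated(study)
  a <- amounts(experimentalSamples(study))
  si <- a * avgDoubleBonds(rd)
  list(species_index = si, class_index = rowsum(si, group = rd$head_class))
}

#' Welch t-test on per-replicate unsaturation indices
#'
#' Two-sample comparison of a class unsaturation index between two groups
#' of replicates (unequal variances, Welch-Satterthwaite df).
#'
#' @param indexA,indexB numeric replicate values (>= 2 each)
#' @return list with \code{t}, \code{df}, \code{p}, and per-group
#'   \code{mean} and \code{se}
#' @export
indexTTest <- function(indexA, indexB) {
  if (length(indexA) < 2L || length(indexB) < 2L)
    stop("need at least 2 replicates per group")
  ht <- stats::t.test(indexA, indexB, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean = c(A = mean(indexA), B = mean(indexB)),
       se = c(A = stats::sd(indexA) / sqrt(length(indexA)),
              B = stats::sd(indexB) / sqrt(length(indexB))))
}

#' Fold-change matrices for heat maps
#'
#' Pivots the contrast results into the two heat-map layouts: per-genotype
#' second-vs-first-treatment log2 fold changes (species x genotype), and
#' per-treatment mutant-vs-reference log2 fold changes (species x genotype,
#' one matrix per treatment). A comparison whose cell is missing yields NA
#' rather than zero. Matching significance masks are attached.
#'
#' @param results data.frame from \code{\link{runContrasts}}
#' @return list with elements \code{treatment_fc} (and
#'   \code{treatment_sig}), \code{genotype_fc} (list per treatment, with
#'   \code{genotype_sig})
#' @export
foldChangeTables <- function(results) {
  pivot <- function(sub, colkey) {
    sp <- sort(unique(sub$species))
    cols <- unique(sub[[colkey]])
    fc <- matrix(NA_real_, length(sp), length(cols),
                 dimnames = list(sp, cols))
    sig <- matrix(NA, length(sp), length(cols), dimnames = list(sp, cols))
    i <- cbind(match(sub$species, sp), match(sub[[colkey]], cols))
    fc[i] <- sub$log2_fc
    sig[i] <- sub$significant
    list(fc = fc, sig = sig)
  }
  out <- list()
  tw <- results[results$contrast_family == "treatment_within_genotype", ]
  if (nrow(tw)) {
    tw$genotype <- sub("^.*\\((.*)\\)$", "\\1", tw$contrast)
    pv <- pivot(tw, "genotype")
    out$treatment_fc <- pv$fc
    out$treatment_sig <- pv$sig
  }
  gw <- results[results$contrast_family == "genotype_within_treatment", ]
  if (nrow(gw)) {
    gw$treatment <- sub("^.*\\((.*)\\)$", "\\1", gw$contrast)
    gw$genotype <- sub(" vs .*$", "", gw$contrast)
    out$genotype_fc <- lapply(split(gw, gw$treatment), function(sub) {
      pv <- pivot(sub, "genotype")
      list(fc = pv$fc, sig = pv$sig)
    })
  }
  out
}

#' Raw-amount fold-change matrices
#'
#' Log2 ratios of per-mg cell-mean amounts (not transformed values):
#' per-genotype second-vs-first-treatment ratios and per-treatment
#' genotype-vs-reference ratios. Unlike the transformed-scale effects of
#' \code{\link{runContrasts}}, these retain the global (per-sample scale)
#' component of a treatment response, which the upper-quartile
#' normalization removes from the inferential results; they are the values
#' a raw-amount fold-change heat map displays. Cells with zero mean yield
#' non-finite entries.
#'
#' @param study an annotated \linkS4class{LipidStudy} in per-mg units
#' @param reference reference genotype (default WT when present)
#' @return list with \code{treatment_fc} (species x genotype) and
#'   \code{genotype_fc} (list per treatment of species x genotype)
#' @export
amountFoldChanges <- function(study, reference = NULL) {
  es <- experimentalSamples(study)
  a <- amounts(es)
  cd <- sampleData(es)
  genos <- unique(cd$genotype)
  trts <- unique(cd$treatment)
  if (is.null(reference))
    reference <- if ("WT" %in% genos) "WT" else genos[1]
  cellmean <- function(g, t)
    rowMeans(a[, cd$genotype == g & cd$treatment == t, drop = FALSE])
  out <- list()
  if (length(trts) >= 2L) {
    out$treatment_fc <- vapply(genos, function(g)
      log2(cellmean(g, trts[2]) / cellmean(g, trts[1])), numeric(nrow(a)))
  }
  out$genotype_fc <- lapply(stats::setNames(trts, trts), function(t)
    vapply(setdiff(genos, reference), function(g)
      log2(cellmean(g, t) / cellmean(reference, t)), numeric(nrow(a))))
  out
}

#' Append aggregate pseudo-analytes to a study
#'
#' Builds a companion \linkS4class{LipidStudy} whose rows are the total
#' lipid, per-class totals and chain-length/double-bond group sums, so the
#' same transformation/moderation/testing machinery that handles species
#' can annotate aggregates with q-values and compact letters. QC columns
#' are dropped (aggregates are for inference, not preprocessing).
#'
#' @param study an annotated \linkS4class{LipidStudy}
#' @return an unannotated \linkS4class{LipidStudy} of pseudo-analytes
#' @export
aggregateStudy <- function(study) {
  es <- experimentalSamples(study)
  ct <- classTotals(study)
  gs <- groupSums(study)
  m <- rbind(total_lipid = ct$total_lipid,
             ct$class_totals,
             gs)
  rownames(m) <- c("total_lipid",
                   paste0("class ", rownames(ct$class_totals)),
                   paste0("group ", rownames(gs)))
  LipidStudy(m, sampleData(es), annotate = FALSE)
}

#' Moderated tests and compact letters for aggregates
#'
#' Runs the transformed pipeline (transformation, precision weights,
#' weighted fits, variance moderation) on the aggregate pseudo-analytes
#' and derives, for each aggregate and treatment, all-pairwise genotype
#' comparisons encoded as compact letters (groups sharing a letter are not
#' significantly different at the q threshold).
#'
#' @param study an annotated \linkS4class{LipidStudy}
#' @param q_threshold significance threshold on q-values
#' @return list with \code{results} (contrast table for aggregates) and
#'   \code{letters} (data.frame aggregate x treatment -> letters)
#' @export
aggregateTests <- function(study, q_threshold = 0.1) {
  agg <- aggregateStudy(study)
  ts <- voomWeights(transformStudy(agg))
  fit <- fitCellMeans(ts)
  mf <- moderateVariances(fit)
  res <- runContrasts(fit, mf, q_threshold = q_threshold)
  trts <- unique(fit@cells$treatment)
  rows <- list()
  for (t in trts) {
    pw <- pairwiseGenotypeTests(fit, mf, treatment = t,
                                q_threshold = q_threshold)
    for (sp in names(pw$significance)) {
      lab <- compactLetters(pw$significance[[sp]])
      rows[[length(rows) + 1L]] <- data.frame(
        aggregate = sp, treatment = t, genotype = names(lab),
        letters = unname(lab), stringsAsFactors = FALSE)
    }
  }
  list(results = res, letters = do.call(rbind, rows))
}
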