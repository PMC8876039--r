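#' @include AllClasses.R AllGenerics.R io.R synthetic.R
NULL

#' Run the full differential lipidomics pipeline
#'
#' Orchestrates preprocessing (QC drift normalization, conversion to per-mg
#' dry weight, LOD and QC-CV filtering), the upper-quartile log2
#' transformation with mean-variance precision weights, per-lipid weighted
#' fits with empirical-Bayes variance moderation, the three contrast
#' families with Storey q-values, aggregation (class totals, group sums,
#' unsaturation indices, fold-change tables, aggregate letters) and PCA.
#'
#' @param study a raw \linkS4class{LipidStudy}
#' @param lod limit of detection on the per-mg scale (0 disables)
#' @param q_threshold significance threshold on q-values
#' @param normalize apply \code{\link{qcNormalize}} (requires QC samples)
#' @param aggregate_tests also run moderated tests and letters on the
#'   aggregate pseudo-analytes
#' @return list with the processed \code{study}, \code{filter_reports},
#'   \code{transformed}, \code{fit}, \code{moderation}, \code{results},
#'   \code{fold_changes}, \code{class_summary}, \code{group_sums},
#'   \code{unsat_index}, \code{pca} and (optionally) \code{aggregates}
#' @export
runPipeline <- function(study, lod = 0, q_threshold = 0.1,
                        normalize = TRUE, aggregate_tests = TRUE) {
  reports <- list()
  if (normalize) study <- qcNormalize(study)
  if (!isTRUE(metadata(study)$per_dry_weight)) study <- perDryWeight(study)
  fl <- filterLOD(study, lod = lod)
  reports$lod <- fl$report
  fc <- filterCV(fl$study)
  reports$cv <- fc$report
  study <- fc$study

  ts <- voomWeights(transformStudy(study))
  fit <- fitCellMeans(ts)
  mf <- moderateVariances(fit)
  results <- runContrasts(fit, mf, q_threshold = q_threshold)

  out <- list(study = study, filter_reports = reports, transformed = ts,
              fit = fit, moderation = mf, results = results,
              fold_changes = foldChangeTables(results),
              class_summary = classTotals(study),
              group_sums = groupSums(study),
              unsat_index = unsaturationIndex(study),
              pca = lipidPCA(study))
  if (aggregate_tests)
    out$aggregates <- aggregateTests(study, q_threshold = q_threshold)
  out
}

.results_files <- c(genotype_within_treatment = "results_genotype_within_treatment.tsv",
                    treatment_within_genotype = "results_treatment_within_genotype.tsv",
                    interaction = "results_interaction.tsv")

#' Write all pipeline outputs to a directory
#'
#' Produces \code{filter_report.tsv}, one results TSV per contrast family,
#' \code{class_totals.tsv}, \code{group_sums.tsv}, \code{unsat_index.tsv},
#' \code{fold_change.tsv}, \code{pca_scores.tsv}, \code{pca_variance.tsv},
#' \code{aggregate_letters.tsv} (when aggregate tests were run) and
#' \code{run_log.txt}.
#'
#' @param res result list from \code{\link{runPipeline}}
#' @param outdir output directory (created if needed)
#' @param seed seed to record in the run log
#' @return invisibly, the paths written
#' @export
writePipelineOutputs <- function(res, outdir, seed = NA_integer_) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- character()
  writeFilterReport(res$filter_reports, p("filter_report.tsv"))
  paths <- c(paths, p("filter_report.tsv"))
  for (fam in unique(res$results$contrast_family)) {
    f <- p(.results_files[[fam]])
    .write_tsv(res$results[res$results$contrast_family == fam, ], f)
    paths <- c(paths, f)
  }
  .write_matrix_tsv(res$class_summary$class_totals, p("class_totals.tsv"),
                    rowlab = "class")
  .write_matrix_tsv(res$group_sums, p("group_sums.tsv"), rowlab = "group")
  .write_matrix_tsv(res$unsat_index$class_index, p("unsat_index.tsv"),
                    rowlab = "class")
  fcl <- res$results[res$results$contrast_family != "interaction",
                     c("contrast_family", "contrast", "species", "log2_fc",
                       "q_value", "significant")]
  colnames(fcl)[2] <- "comparison"
  .write_tsv(fcl, p("fold_change.tsv"))
  .write_matrix_tsv(pcaScores(res$pca), p("pca_scores.tsv"),
                    rowlab = "sample_id")
  .write_tsv(data.frame(component = seq_along(res$pca@var_explained),
                        var_explained_pct = varExplained(res$pca)),
             p("pca_variance.tsv"))
  if (!is.null(res$aggregates))
    .write_tsv(res$aggregates$letters, p("aggregate_letters.tsv"))
  writeLines(c(sprintf("lipidiff %s", as.character(utils::packageVersion("lipidiff"))),
               sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("seed: %s", seed),
               sprintf("species retained: %d", nrow(res$study)),
               sprintf("moderation: d0 = %g, s0_sq = %g",
                       priorDf(res$moderation), priorVar(res$moderation))),
             p("run_log.txt"))
  invisible(c(paths, p("class_totals.tsv"), p("group_sums.tsv"),
              p("unsat_index.tsv"), p("fold_change.tsv"),
              p("pca_scores.tsv"), p("pca_variance.tsv"), p("run_log.txt")))
}

.cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Simulate a study and write its files
#'
#' Writes \code{amounts.tsv}, \code{samples.tsv} and
#' \code{ground_truth.tsv} (columns species, contrast_family, contrast,
#' true_log2fc, is_null) to \code{outdir}.
#'
#' @param config list of \code{\link{simConfig}} overrides (e.g. parsed
#'   from YAML)
#' @param outdir output directory
#' @param seed seed overriding the config seed
#' @export
cmdSimulate <- function(config = list(), outdir, seed = NULL) {
  known <- names(formals(simConfig))
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown simulate config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cfg <- do.call(simConfig, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generateStudy(cfg)
  writeStudy(gen$study, file.path(outdir, "amounts.tsv"),
             file.path(outdir, "samples.tsv"))
  .write_tsv(gen$truth$contrasts, file.path(outdir, "ground_truth.tsv"))
  invisible(gen)
}

#' Run the pipeline on TSV inputs and write outputs
#'
#' @param amounts_path,samples_path input TSVs (see \code{\link{readStudy}})
#' @param outdir output directory
#' @param lod,q_threshold,normalize passed to \code{\link{runPipeline}}
#' @param seed recorded in the run log
#' @export
cmdRun <- function(amounts_path, samples_path, outdir, lod = 0,
                   q_threshold = 0.1, normalize = TRUE, seed = NA_integer_) {
  study <- readStudy(amounts_path, samples_path)
  res <- runPipeline(study, lod = lod, q_threshold = q_threshold,
                     normalize = normalize)
  writePipelineOutputs(res, outdir, seed = seed)
  invisible(res)
}

#' Extract and score ion images from a pixel TSV
#'
#' Writes \code{ion_image_<mz>.tsv} per target m/z (all on a common
#' display scale) and \code{uniformity.tsv} with the dispersion and
#' spatial-autocorrelation statistics on the TIC tissue mask.
#'
#' @param pixels_path long pixel TSV (columns x, y, mz, intensity)
#' @param mz numeric vector of target m/z values
#' @param outdir output directory
#' @param tol mass tolerance in Da
#' @param raster pixel pitch in micrometres
#' @param mask_quantile TIC quantile defining the tissue mask
#' @export
cmdMSI <- function(pixels_path, mz, outdir, tol = 0.01, raster = 100,
                   mask_quantile = 0.1) {
  if (missing(mz) || !length(mz)) stop("at least one --mz target is required")
  if (tol <= 0) stop("tol must be positive")
  pixels <- readPixels(pixels_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  images <- lapply(mz, function(m)
    extractIonImage(pixels, m, tol = tol, pixel_size = raster))
  mask <- tissueMask(pixels, probs = mask_quantile)
  rows <- list()
  for (k in seq_along(mz)) {
    st <- uniformityStat(images[[k]], mask)
    rows[[k]] <- data.frame(target_mz = mz[k], qcd = st$qcd,
                            morans_i = st$morans_i,
                            degenerate = st$degenerate)
  }
  # per-metabolite display scales are common across the set by construction
  for (k in seq_along(mz))
    writeIonImage(images[[k]],
                  file.path(outdir, sprintf("ion_image_%g.tsv", mz[k])))
  .write_tsv(do.call(rbind, rows), file.path(outdir, "uniformity.tsv"))
  invisible(images)
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{simulate}, \code{run} and \code{msi}
#' (see \code{inst/scripts/lipidiff}). Global flags: \code{--config}
#' (YAML), \code{--outdir}, \code{--seed}. Returns 0 on success, 2 on a
#' validation error.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status
#' @export
lipidiffCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lipidiff <simulate|run|msi> [--config FILE] [--outdir DIR]",
    "[--seed N] [--amounts FILE] [--samples FILE] [--pixels FILE]",
    "[--mz M1,M2,...] [--tol T] [--raster R]")
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      message("malformed option: ", rest[i]); return(2L)
    }
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  outdir <- .cfg_get(opts, "outdir", .cfg_get(cfg, "outdir", "lipidiff_out"))
  seed <- as.integer(.cfg_get(opts, "seed", .cfg_get(cfg, "seed", 1L)))
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cmdSimulate(.cfg_get(cfg, "simulate", list()), outdir, seed = seed)
        0L
      },
      run = {
        cmdRun(.cfg_get(opts, "amounts", file.path(outdir, "amounts.tsv")),
               .cfg_get(opts, "samples", file.path(outdir, "samples.tsv")),
               outdir,
               lod = as.numeric(.cfg_get(cfg, "lod", 0)),
               q_threshold = as.numeric(.cfg_get(cfg, "q_threshold", 0.1)),
               seed = seed)
        0L
      },
      msi = {
        if (is.null(opts$pixels)) stop("--pixels FILE is required")
        if (is.null(opts$mz)) stop("--mz is required")
        cmdMSI(opts$pixels,
               mz = as.numeric(strsplit(opts$mz, ",")[[1]]),
               outdir = outdir,
               tol = as.numeric(.cfg_get(opts, "tol", 0.01)),
               raster = as.numeric(.cfg_get(opts, "raster", 100)))
        0L
      },
      { message("unknown command: ", cmd); message(usage); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 2L })
  status
}
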