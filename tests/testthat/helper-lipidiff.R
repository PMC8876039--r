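# Builders for small hand-constructed studies used across the tests.

suppressPackageStartupMessages({
  library(SummarizedExperiment)   # assay(), colData(), metadata()
})

sampleSheet <- function(n, genotype = "WT", treatment = "+N",
                        is_qc = FALSE, dry_weight_mg = 1,
                        run_order = seq_len(n), ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  data.frame(sample_id = ids,
             genotype = rep_len(genotype, n),
             treatment = rep_len(treatment, n),
             replicate = seq_len(n),
             is_qc = rep_len(is_qc, n),
             dry_weight_mg = rep_len(dry_weight_mg, n),
             run_order = run_order,
             stringsAsFactors = FALSE)
}

toyStudy <- function(amounts, samples = NULL, annotate = TRUE) {
  if (is.null(rownames(amounts)))
    rownames(amounts) <- sprintf("PC %d:1", 30 + 2 * seq_len(nrow(amounts)))
  if (is.null(colnames(amounts)))
    colnames(amounts) <- sprintf("s%02d", seq_len(ncol(amounts)))
  if (is.null(samples)) samples <- sampleSheet(ncol(amounts))
  samples$sample_id <- colnames(amounts)
  LipidStudy(amounts, samples, annotate = annotate)
}

# two genotype groups, one treatment, unit dry weights, no QC
twoGroupStudy <- function(amounts, n_per_group = ncol(amounts) / 2) {
  sm <- sampleSheet(ncol(amounts),
                    genotype = rep(c("WT", "mut"), each = n_per_group))
  toyStudy(amounts, sm)
}
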