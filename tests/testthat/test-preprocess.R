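qcToyStudy <- function(exp_vals, qc_vals, qc_runs, exp_runs) {
  # one analyte, experimental samples + QC injections with given run orders
  n <- length(exp_vals) + length(qc_vals)
  a <- matrix(c(exp_vals, qc_vals), nrow = 1,
              dimnames = list("PC 34:2", sprintf("s%02d", seq_len(n))))
  sm <- sampleSheet(n, is_qc = rep(c(FALSE, TRUE),
                                   c(length(exp_vals), length(qc_vals))),
                    run_order = c(exp_runs, qc_runs))
  sm$genotype[sm$is_qc] <- NA
  sm$treatment[sm$is_qc] <- NA
  sm$dry_weight_mg[sm$is_qc] <- NA
  toyStudy(a, sm)
}

test_that("constant QC intensity leaves experimental values unchanged", {
  st <- qcToyStudy(exp_vals = c(3, 7), qc_vals = c(5, 5, 5),
                   qc_runs = c(1, 3, 5), exp_runs = c(2, 4))
  norm <- qcNormalize(st)
  expect_equal(amounts(norm)[1, 1:2], amounts(st)[1, 1:2])
  expect_true(metadata(norm)$qc_normalized)
})

test_that("linearly drifting QC is corrected by interpolation", {
  # QC triples 10 -> 20 -> 30 over the run; experimental at runs 2 and 4
  # see interpolated references 15 and 25 and the grand QC median 20
  st <- qcToyStudy(exp_vals = c(100, 100), qc_vals = c(10, 20, 30),
                   qc_runs = c(1, 3, 5), exp_runs = c(2, 4))
  norm <- qcNormalize(st)
  expect_equal(unname(amounts(norm)[1, 1:2]),
               c(100 / 15 * 20, 100 / 25 * 20))
  # QC columns themselves are untouched (raw CVs feed the filter)
  expect_equal(unname(amounts(norm)[1, 3:5]), c(10, 20, 30))
})

test_that("interpolation clamps at the run ends", {
  # experimental sample before the first QC uses the first QC value
  st <- qcToyStudy(exp_vals = 60, qc_vals = c(10, 30),
                   qc_runs = c(2, 4), exp_runs = 1)
  expect_equal(unname(amounts(qcNormalize(st))[1, 1]), 60 / 10 * 20)
})

test_that("all-zero QC analytes pass through flagged; absent QC errors", {
  a <- matrix(c(5, 6, 0, 0, 0,
                5, 6, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("PC 34:1", "PC 36:2"), sprintf("s%d", 1:5)))
  sm <- sampleSheet(5, is_qc = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  st <- toyStudy(a, sm)
  expect_warning(norm <- qcNormalize(st), "all-zero QC")
  expect_equal(amounts(norm)["PC 34:1", ], amounts(st)["PC 34:1", ])
  expect_equal(metadata(norm)$qc_uncorrected, "PC 34:1")

  noqc <- toyStudy(a[, 1:2], sampleSheet(2))
  expect_error(qcNormalize(noqc), "skip")
})

test_that("QC CV filter removes CV > 0.3, strictly", {
  a <- rbind("PC 34:1" = c(1, 1, 10, 10, 10),      # CV 0
             "PC 34:2" = c(1, 1, 5, 10, 15),       # CV 0.5, removed
             "PC 34:3" = c(1, 1, 7, 10, 13),       # CV 0.3 exactly, kept
             "PC 34:4" = c(1, 1, 0, 0, 0))         # zero mean -> removed
  colnames(a) <- sprintf("s%d", 1:5)
  st <- toyStudy(a, sampleSheet(5, is_qc = c(FALSE, FALSE, TRUE, TRUE, TRUE)))
  out <- filterCV(st)
  expect_equal(unname(out$report@cv_values),
               c(0, 0.5, 0.3, Inf))
  expect_setequal(out$report@removed_cv, c("PC 34:2", "PC 34:4"))
  expect_setequal(rownames(out$study), c("PC 34:1", "PC 34:3"))
})

test_that("LOD filter uses the mean over experimental samples", {
  a <- rbind("PC 34:1" = c(0.4, 0.6, 9),    # mean 0.5 < 1 -> removed
             "PC 34:2" = c(1.0, 1.2, 9))    # mean 1.1 kept
  colnames(a) <- sprintf("s%d", 1:3)
  st <- toyStudy(a, sampleSheet(3, is_qc = c(FALSE, FALSE, TRUE)))
  out <- filterLOD(st, lod = 1)
  expect_equal(out$report@removed_lod, "PC 34:1")
  expect_equal(rownames(out$study), "PC 34:2")
  # lod = 0 disables the filter; negative lod is rejected
  expect_length(filterLOD(st, 0)$report@removed_lod, 0L)
  expect_error(filterLOD(st, -1), "non-negative")
})

test_that("LOD and CV filters commute on the retained set", {
  gen <- generateStudy(simConfig(seed = 3, n_cv_violators = 4,
                                 n_lod_violators = 3, lod_level = 0.005))
  st <- perDryWeight(gen$study)
  a <- rownames(filterCV(filterLOD(st, 0.005)$study)$study)
  b <- rownames(filterLOD(filterCV(st)$study, 0.005)$study)
  expect_equal(sort(a), sort(b))
})

test_that("planted LOD and CV violators are exactly the filtered species", {
  gen <- generateStudy(simConfig(seed = 11, n_cv_violators = 5,
                                 n_lod_violators = 4, lod_level = 0.005,
                                 lod_censor = 0))
  st <- perDryWeight(gen$study)
  fl <- filterLOD(st, lod = 0.005)
  expect_setequal(fl$report@removed_lod, gen$truth$lod_violators)
  fc <- filterCV(fl$study)
  expect_setequal(fc$report@removed_cv, gen$truth$cv_violators)
})

test_that("dry-weight conversion divides experimental columns once", {
  a <- matrix(c(2, 4, 10, 10), nrow = 1,
              dimnames = list("PC 34:2", sprintf("s%d", 1:4)))
  sm <- sampleSheet(4, is_qc = c(FALSE, FALSE, TRUE, TRUE),
                    dry_weight_mg = c(2, 1, NA, NA))
  st <- toyStudy(a, sm)
  out <- perDryWeight(st)
  expect_equal(unname(amounts(out)[1, ]), c(1, 4, 10, 10))
  expect_error(perDryWeight(out), "already")
  sm$dry_weight_mg[1] <- NA
  expect_error(perDryWeight(toyStudy(a, sm)), "s1")
})

test_that("filter report TSV lists removals with reasons", {
  rep_cv <- new("FilterReport", removed_lod = character(),
                removed_cv = "PC 34:2", cv_values = c("PC 34:2" = 0.5))
  rep_lod <- new("FilterReport", removed_lod = "PE 36:4",
                 removed_cv = character(), cv_values = numeric())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFilterReport(list(rep_lod, rep_cv), f)
  back <- read.delim(f)
  expect_equal(back$species, c("PC 34:2", "PE 36:4"))
  expect_equal(back$reason, c("cv", "lod"))
})
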