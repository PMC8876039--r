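test_that("class totals, fractions and total lipid match brute force", {
  a <- rbind("PC 34:2" = c(3, 6), "PC 36:4" = c(1, 1),
             "PE 34:2" = c(1, 2), "LPC 18:1" = c(1, 1))
  colnames(a) <- c("s01", "s02")
  ct <- classTotals(toyStudy(a))
  expect_equal(ct$class_totals["PC", ], c(s01 = 4, s02 = 7))
  expect_equal(ct$total_lipid, c(s01 = 6, s02 = 10))
  expect_equal(colSums(ct$mol_fraction), c(s01 = 1, s02 = 1))
  expect_equal(ct$mol_fraction["LPC", "s01"], 1 / 6)
  # lyso classes count towards the total
  expect_equal(colSums(ct$class_totals), ct$total_lipid)
})

test_that("conservation identities hold on a full synthetic study", {
  gen <- generateStudy(simConfig(seed = 5))
  st <- perDryWeight(gen$study)
  a <- amounts(experimentalSamples(st))
  ct <- classTotals(st)
  gs <- groupSums(st)
  expect_equal(colSums(ct$class_totals), colSums(a), tolerance = 1e-12)
  expect_equal(colSums(gs), colSums(a), tolerance = 1e-12)
  expect_equal(ct$total_lipid, colSums(a), tolerance = 1e-12)
  # brute force per class
  rd <- speciesData(st)
  for (cl in unique(rd$head_class))
    expect_equal(ct$class_totals[cl, ],
                 colSums(a[rd$head_class == cl, , drop = FALSE]),
                 tolerance = 1e-12)
})

test_that("group sums merge head classes and omit absent keys", {
  a <- rbind("PE 36:6" = c(2), "PC 36:6" = c(3), "PC 34:1" = c(5))
  colnames(a) <- "s01"
  gs <- groupSums(toyStudy(a))
  expect_equal(gs["36:6", "s01"], 5)
  expect_false("42:3" %in% rownames(gs))
})

test_that("unsaturation indices follow amount times double bonds per chain", {
  a <- rbind("PE 34:2" = c(3), "PE 36:6" = c(1), "PS 40:0" = c(7),
             "LPC 18:1" = c(2))
  colnames(a) <- "s01"
  ui <- unsaturationIndex(toyStudy(a))
  expect_equal(ui$species_index["PE 34:2", "s01"], 3)    # 3 * (2/2)
  expect_equal(ui$species_index["PS 40:0", "s01"], 0)    # saturated
  expect_equal(ui$species_index["LPC 18:1", "s01"], 2)   # 2 * (1/1)
  expect_equal(ui$class_index["PE", "s01"], 3 * 1 + 1 * 3)
  # linearity in amounts
  ui2 <- unsaturationIndex(toyStudy(a * 2.5))
  expect_equal(ui2$class_index, ui$class_index * 2.5)
})

test_that("uniform-unsaturation classes obey the closed form", {
  # all PE species with avg double bonds b = 2 -> class index = b * total
  a <- rbind("PE 34:4" = c(2, 3), "PE 36:4" = c(5, 1), "PE 38:4" = c(4, 4))
  colnames(a) <- c("s01", "s02")
  st <- toyStudy(a)
  ui <- unsaturationIndex(st)
  ct <- classTotals(st)
  expect_equal(ui$class_index["PE", ], 2 * ct$class_totals["PE", ])
})

test_that("the Welch index test matches hand computation and guards inputs", {
  tt <- indexTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4, tolerance = 1e-12)
  expect_equal(tt$p, 0.02131164, tolerance = 1e-6)
  expect_equal(unname(tt$mean), c(2, 5))
  expect_equal(unname(tt$se), rep(1 / sqrt(3), 2))
  same <- indexTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(indexTTest(1, c(1, 2)), "2 replicates")
})

test_that("a planted 30% index reduction is detected at n = 3", {
  # power of the Welch test on PS/PE class indices across generator seeds
  cfg_args <- list(replicates = c(default = 3L), pufa_vlc_mult = 0.4)
  hits <- 0L
  n_rep <- 15L
  for (seed in seq_len(n_rep)) {
    gen <- generateStudy(do.call(simConfig, c(cfg_args, seed = 100 + seed)))
    st <- perDryWeight(gen$study)
    ui <- unsaturationIndex(st)$class_index
    cd <- sampleData(experimentalSamples(st))
    pick <- function(g) cd$sample_id[cd$genotype == g & cd$treatment == "-N"]
    p_pe <- indexTTest(ui["PE", pick("WT")], ui["PE", pick("atg7")])$p
    p_ps <- indexTTest(ui["PS", pick("WT")], ui["PS", pick("atg7")])$p
    # planted reductions exceed 30% of the class index for PE and PS
    expect_lt(mean(ui["PE", pick("atg7")]), mean(ui["PE", pick("WT")]))
    if (p_pe < 0.05 && p_ps < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("fold-change tables pivot contrasts with missing cells flagged", {
  res <- data.frame(
    species = rep(c("PC 34:2", "PE 36:4"), each = 2),
    contrast_family = "treatment_within_genotype",
    contrast = rep(c("-N vs +N (WT)", "-N vs +N (atg5)"), 2),
    log2_fc = c(-1, -0.5, 0.2, NA),
    stat = 0, p_value = 0.5, q_value = 0.5,
    significant = c(TRUE, FALSE, FALSE, NA))
  ft <- foldChangeTables(res)
  expect_equal(dim(ft$treatment_fc), c(2L, 2L))
  expect_equal(ft$treatment_fc["PC 34:2", "WT"], -1)
  expect_true(is.na(ft$treatment_fc["PE 36:4", "atg5"]))
})

test_that("raw-amount fold changes retain the global treatment component", {
  gen <- generateStudy(simConfig(seed = 8, lod_censor = 0, noise_cv = 0.05))
  st <- perDryWeight(qcNormalize(gen$study))
  afc <- amountFoldChanges(st)
  rd <- speciesData(st)
  ordinary <- !(rd$head_class %in% c("LPC", "LPE", "LPG", "PA"))
  # ordinary species decrease ~ log2(0.55) under -N in unblocked genotypes
  med <- median(afc$treatment_fc[ordinary, "rns2"])
  expect_lt(abs(med - log2(0.55)), 0.3)
  lyso <- rd$head_class %in% c("LPC", "LPE", "LPG")
  expect_gt(median(afc$treatment_fc[lyso, "rns2"]), 0.5)
})

test_that("aggregate pseudo-analytes run through the testing machinery", {
  gen <- generateStudy(simConfig(seed = 13))
  st <- suppressWarnings(perDryWeight(qcNormalize(gen$study)))
  at <- aggregateTests(st)
  expect_true("total_lipid" %in% at$results$species)
  expect_true(any(grepl("^class ", at$results$species)))
  expect_true(any(grepl("^group ", at$results$species)))
  lt <- at$letters
  expect_setequal(unique(lt$treatment), c("+N", "-N"))
  expect_true(all(nchar(lt$letters) >= 1))
})
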