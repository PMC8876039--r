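#' @include AllClasses.R AllGenerics.R
NULL

#' Default glycerolipid species catalog
#'
#' A fixed 120-species dictionary over the eleven head-group classes with
#' Arabidopsis-realistic carbon:double-bond ranges: C16/C18 plastidic and
#' extraplastidic combinations for the galactolipids (34:x, 36:x, with the
#' highly unsaturated 34:6/36:6 typical of plastid membranes), 32-40
#' carbons for PC/PE/PI/PA/PG, the very-long-chain 40-44 carbon species
#' characteristic of Arabidopsis PS, and single-chain 16:x/18:x
#' lysophospholipids.
#'
#' @return data.frame with columns \code{head_class}, \code{total_carbons},
#'   \code{double_bonds}
#' @export
defaultCatalog <- function() {
  mk <- function(cls, cd) data.frame(
    head_class = cls,
    total_carbons = as.integer(sub(":.*", "", cd)),
    double_bonds = as.integer(sub(".*:", "", cd)),
    stringsAsFactors = FALSE)
  gal <- c(paste0("34:", 1:6), paste0("36:", 1:6))
  rbind(
    mk("MGDG", gal),
    mk("DGDG", gal),
    mk("PG",   c("32:0", "32:1", "34:0", "34:1", "34:2", "34:3", "34:4")),
    mk("PC",   c("32:0", paste0("34:", 1:4), paste0("36:", 1:6),
                 paste0("38:", 2:6), "40:2", "40:3")),
    mk("PE",   c(paste0("34:", 1:3), paste0("36:", 1:6), paste0("38:", 2:6),
                 "40:2", "40:3", "40:4", "42:2", "42:3")),
    mk("PI",   c("32:0", paste0("34:", 1:3), paste0("36:", 1:6))),
    mk("PS",   c("34:1", "34:2", "36:1", "36:2", "38:2", "38:3", "38:4",
                 "40:1", "40:2", "40:3", "42:1", "42:2", "42:3",
                 "44:2", "44:3")),
    mk("PA",   c("32:0", paste0("34:", 1:4), paste0("36:", 2:6),
                 "38:3", "38:4")),
    mk("LPC",  c("16:0", "16:1", "18:0", "18:1", "18:2", "18:3")),
    mk("LPE",  c("16:0", "16:1", "18:0", "18:1", "18:2", "18:3")),
    mk("LPG",  c("16:0", "18:1", "18:2")))
}

.BLOCKED_GENOTYPES <- c("atg5", "atg7", "atg9", "kin10",
                        "rns2;atg5", "rns2;atg9")

# Polyunsaturated / very-long-chain species affected in autophagy-blocked
# genotypes under -N: the 36:6 and 38:4-38:6 groups plus all species with
# 40 or more acyl carbons (the very-long-chain PS/PE/PC region, including
# 42:2 and 42:3). The bulk 34:x plastidic galactolipids are deliberately
# outside the set, which also keeps the per-sample upper quartile (the
# transformation's normalization reference) stable across cells.
.pufa_vlc_target <- function(cat_) {
  (cat_$total_carbons >= 38L & cat_$double_bonds >= 4L) |
    cat_$total_carbons >= 40L |
    (cat_$total_carbons == 36L & cat_$double_bonds == 6L)
}

#' Configuration of a synthetic autophagy lipidomics study
#'
#' Defaults emulate the structure of a nine-genotype Arabidopsis seedling
#' experiment under nitrogen-replete (+N) and nitrogen-starved (-N)
#' growth: 3 biological replicates per genotype and treatment (2 for WT
#' and atg5), 120 glycerolipid species, interleaved QC-pool injections
#' with slow multiplicative instrument drift, left-censored zeros, a
#' global -N decrease with a lysophospholipid/PA increase, and an
#' additional decrease of polyunsaturated and very-long-chain species
#' (the 36:6 and 38:4-38:6 groups and all species with >= 40 acyl
#' carbons) confined to autophagy-blocked genotypes under -N.
#'
#' Class base amounts are order-of-magnitude placeholders on a nmol/mg
#' scale with MGDG the dominant class. Within-class species weights favour
#' highly unsaturated galactolipid and PC/PE species and long-chain PS
#' species, mirroring typical Arabidopsis leaf profiles.
#'
#' @param n_species number of species drawn from the catalog (<= 120)
#' @param genotypes genotype labels; the first is the reference (WT)
#' @param blocked_genotypes genotypes whose autophagy is blocked (receive
#'   the PUFA/VLC effect under -N)
#' @param replicates named replicate counts; unnamed default applies to all
#' @param treatments two treatment labels, reference first
#' @param n_qc number of interleaved QC-pool injections
#' @param drift_amplitude relative amplitude of the linear intensity drift
#' @param noise_cv biological + technical coefficient of variation of
#'   experimental observations (lognormal, multiplicative)
#' @param qc_cv technical CV of QC injections around the drift curve
#' @param nstarve_mult -N vs +N multiplier for ordinary species (< 1)
#' @param lysopa_mult -N vs +N multiplier for lyso and PA species (> 1)
#' @param pufa_vlc_mult multiplier applied to polyunsaturated/very-long-
#'   chain species in blocked genotypes under -N (< 1)
#' @param lod_censor amounts (per mg scale) below this are reported as 0
#' @param n_cv_violators species planted with excessive QC variability
#' @param violator_cv QC CV planted for those species
#' @param n_lod_violators species planted with abundance below
#'   \code{lod_level}
#' @param lod_level the detection limit that those violators must undercut
#' @param seed integer random seed; fixed seed reproduces the study exactly
#' @return a \code{SimConfig} list
#' @export
simConfig <- function(n_species = 120L,
                      genotypes = c("WT", "atg5", "atg7", "atg9", "kin10",
                                    "raptor1b", "rns2", "rns2;atg5",
                                    "rns2;atg9"),
                      blocked_genotypes = .BLOCKED_GENOTYPES,
                      replicates = c(WT = 2L, atg5 = 2L, default = 3L),
                      treatments = c("+N", "-N"),
                      n_qc = 7L,
                      drift_amplitude = 0.15,
                      noise_cv = 0.15,
                      qc_cv = 0.05,
                      nstarve_mult = 0.55,
                      lysopa_mult = 2.0,
                      pufa_vlc_mult = 0.4,
                      lod_censor = 0.02,
                      n_cv_violators = 0L,
                      violator_cv = 0.8,
                      n_lod_violators = 0L,
                      lod_level = 0.01,
                      seed = 1L) {
  cfg <- list(n_species = as.integer(n_species), genotypes = genotypes,
              blocked_genotypes = blocked_genotypes, replicates = replicates,
              treatments = treatments, n_qc = as.integer(n_qc),
              drift_amplitude = drift_amplitude, noise_cv = noise_cv,
              qc_cv = qc_cv, nstarve_mult = nstarve_mult,
              lysopa_mult = lysopa_mult, pufa_vlc_mult = pufa_vlc_mult,
              lod_censor = lod_censor,
              n_cv_violators = as.integer(n_cv_violators),
              violator_cv = violator_cv,
              n_lod_violators = as.integer(n_lod_violators),
              lod_level = lod_level, seed = as.integer(seed))
  if (cfg$n_species < 1L || cfg$n_species > nrow(defaultCatalog()))
    stop("n_species must be between 1 and ", nrow(defaultCatalog()))
  if (any(c(cfg$nstarve_mult, cfg$lysopa_mult, cfg$pufa_vlc_mult) <= 0))
    stop("effect multipliers must be positive")
  reps <- .rep_counts(cfg)
  if (any(reps < 1L)) stop("replicate counts must be >= 1")
  if (length(cfg$treatments) < 1L) stop("at least one treatment required")
  class(cfg) <- "SimConfig"
  cfg
}

.rep_counts <- function(cfg) {
  dflt <- if ("default" %in% names(cfg$replicates))
    cfg$replicates[["default"]] else 3L
  vapply(cfg$genotypes, function(g) {
    if (g %in% names(cfg$replicates)) as.integer(cfg$replicates[[g]])
    else as.integer(dflt)
  }, 1L)
}

.class_base <- c(MGDG = 60, DGDG = 30, PC = 25, PE = 15, PG = 12, PI = 8,
                 PA = 3, PS = 2, LPC = 0.4, LPE = 0.25, LPG = 0.12)

#' Generate a synthetic lipidomics study with ground truth
#'
#' Draws per-species true abundances (lognormal within-class weights around
#' the class base amounts), applies the configured treatment and
#' genotype-by-treatment multipliers, multiplies by per-observation
#' lognormal noise of the configured CV and by the sample's dry weight and
#' the run-order drift curve (so the raw matrix looks like instrument
#' intensities), censors amounts below the detection threshold to zero,
#' and appends QC-pool injections (pooled mean times drift times technical
#' noise). The returned ground truth records the true log2 effect and
#' null flag of every species under every contrast the differential
#' pipeline tests, the planted LOD/CV violators, and the drift curve.
#'
#' Output is byte-identical for a fixed seed.
#'
#' @param cfg a \code{\link{simConfig}} configuration
#' @return list with \code{study} (a \linkS4class{LipidStudy} of raw
#'   intensities) and \code{truth}
#' @export
generateStudy <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  cat_ <- defaultCatalog()[seq_len(cfg$n_species), ]
  species <- sprintf("%s %d:%d", cat_$head_class, cat_$total_carbons,
                     cat_$double_bonds)
  # within-class composition: lognormal spread plus biology-motivated biases
  bias <- numeric(nrow(cat_))
  gal <- cat_$head_class %in% c("MGDG", "DGDG")
  pcpe <- cat_$head_class %in% c("PC", "PE")
  bias[gal] <- 0.35 * cat_$double_bonds[gal]
  bias[pcpe] <- 0.25 * cat_$double_bonds[pcpe]
  ps <- cat_$head_class == "PS"
  bias[ps] <- 0.15 * (cat_$total_carbons[ps] - 34)
  wgt <- exp(stats::rnorm(nrow(cat_), 0, 0.8) + bias)
  base <- numeric(nrow(cat_))
  for (cl in unique(cat_$head_class)) {
    sel <- cat_$head_class == cl
    base[sel] <- .class_base[[cl]] * wgt[sel] / sum(wgt[sel])
  }

  lod_violators <- cv_violators <- character()
  if (cfg$n_lod_violators > 0L) {
    lod_violators <- species[order(base)[seq_len(cfg$n_lod_violators)]]
    base[species %in% lod_violators] <- cfg$lod_level * 0.1
  }
  if (cfg$n_cv_violators > 0L) {
    pool <- setdiff(species, lod_violators)
    cv_violators <- sample(pool, cfg$n_cv_violators)
  }

  lysopa <- cat_$head_class %in% c(LYSO_CLASSES, "PA")
  target <- .pufa_vlc_target(cat_)
  trtA <- cfg$treatments[1]
  two_trt <- length(cfg$treatments) >= 2L
  trtB <- if (two_trt) cfg$treatments[2] else NA_character_

  mult <- function(genotype, treatment) {
    m <- rep(1, nrow(cat_))
    if (two_trt && treatment == trtB) {
      m <- ifelse(lysopa, cfg$lysopa_mult, cfg$nstarve_mult)
      if (genotype %in% cfg$blocked_genotypes)
        m[target] <- m[target] * cfg$pufa_vlc_mult
    }
    m
  }

  reps <- .rep_counts(cfg)
  sm <- do.call(rbind, lapply(cfg$treatments, function(t)
    do.call(rbind, lapply(cfg$genotypes, function(g)
      data.frame(genotype = g, treatment = t,
                 replicate = seq_len(reps[[g]]),
                 stringsAsFactors = FALSE)))))
  sm$sample_id <- sprintf("%s_%s_r%d", gsub("[;]", ".", sm$genotype),
                          sm$treatment, sm$replicate)
  sm$is_qc <- FALSE
  n_exp <- nrow(sm)
  n_total <- n_exp + cfg$n_qc
  qc_pos <- if (cfg$n_qc > 0L)
    unique(round(seq(1, n_total, length.out = cfg$n_qc))) else integer()
  exp_pos <- sample(setdiff(seq_len(n_total), qc_pos))
  sm$run_order <- exp_pos
  sm$dry_weight_mg <- stats::runif(n_exp, 1.5, 3.0)

  drift <- function(o) 1 + cfg$drift_amplitude * (2 * (o - 1) / (n_total - 1) - 1)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))

  amounts <- matrix(0, nrow(cat_), n_exp,
                    dimnames = list(species, sm$sample_id))
  true_mean <- matrix(0, nrow(cat_), n_exp)
  for (s in seq_len(n_exp)) {
    mu <- base * mult(sm$genotype[s], sm$treatment[s])
    true_mean[, s] <- mu
    obs <- mu * exp(stats::rnorm(nrow(cat_), 0, sdlog))
    obs[obs < cfg$lod_censor] <- 0
    amounts[, s] <- obs * sm$dry_weight_mg[s] * drift(sm$run_order[s])
  }

  if (cfg$n_qc > 0L) {
    pool <- rowMeans(true_mean)
    sd_qc <- sqrt(log(1 + cfg$qc_cv^2))
    qc <- vapply(seq_along(qc_pos), function(k) {
      sd_i <- ifelse(species %in% cv_violators,
                     sqrt(log(1 + cfg$violator_cv^2)), sd_qc)
      v <- pool * drift(qc_pos[k]) * exp(stats::rnorm(nrow(cat_), 0, sd_i))
      v[v < cfg$lod_censor] <- 0
      v
    }, numeric(nrow(cat_)))
    colnames(qc) <- sprintf("QC_%02d", seq_along(qc_pos))
    qcm <- data.frame(genotype = NA_character_, treatment = NA_character_,
                      replicate = NA_integer_, sample_id = colnames(qc),
                      is_qc = TRUE, run_order = qc_pos,
                      dry_weight_mg = NA_real_, stringsAsFactors = FALSE)
    amounts <- cbind(amounts, qc)
    sm <- rbind(sm, qcm[, colnames(sm)])
  }

  truth <- .ground_truth(cfg, cat_, species, lysopa, target)
  study <- LipidStudy(amounts, sm)
  list(study = study,
       truth = list(contrasts = truth,
                    lod_violators = lod_violators,
                    cv_violators = cv_violators,
                    target_species = species[target],
                    drift = data.frame(run_order = seq_len(n_total),
                                       factor = drift(seq_len(n_total))),
                    base_amounts = stats::setNames(base, species),
                    config = cfg))
}

.ground_truth <- function(cfg, cat_, species, lysopa, target) {
  if (length(cfg$treatments) < 2L)
    return(data.frame(species = character(), contrast_family = character(),
                      contrast = character(), true_log2fc = numeric(),
                      is_null = logical()))
  trtA <- cfg$treatments[1]; trtB <- cfg$treatments[2]
  ref <- cfg$genotypes[1]
  rows <- list()
  trt_fc <- function(g) {
    fc <- ifelse(lysopa, log2(cfg$lysopa_mult), log2(cfg$nstarve_mult))
    if (g %in% cfg$blocked_genotypes)
      fc[target] <- fc[target] + log2(cfg$pufa_vlc_mult)
    fc
  }
  for (t in cfg$treatments)
    for (g in setdiff(cfg$genotypes, ref)) {
      fc <- if (t == trtB) trt_fc(g) - trt_fc(ref) else rep(0, nrow(cat_))
      rows[[length(rows) + 1L]] <- data.frame(
        species = species, contrast_family = "genotype_within_treatment",
        contrast = sprintf("%s vs %s (%s)", g, ref, t),
        true_log2fc = fc, is_null = fc == 0, stringsAsFactors = FALSE)
    }
  for (g in cfg$genotypes) {
    fc <- trt_fc(g)
    rows[[length(rows) + 1L]] <- data.frame(
      species = species, contrast_family = "treatment_within_genotype",
      contrast = sprintf("%s vs %s (%s)", trtB, trtA, g),
      true_log2fc = fc, is_null = fc == 0, stringsAsFactors = FALSE)
  }
  for (g in setdiff(cfg$genotypes, ref)) {
    fc <- trt_fc(g) - trt_fc(ref)
    rows[[length(rows) + 1L]] <- data.frame(
      species = species, contrast_family = "interaction",
      contrast = sprintf("(%s vs %s) x (%s vs %s)", g, ref, trtB, trtA),
      true_log2fc = fc, is_null = fc == 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a two-group null-plus-effects benchmark study
#'
#' A large flat design for error-rate benchmarking: \code{n_species}
#' lipids, two genotypes with \code{n_per_group} replicates each under a
#' single treatment, lognormal abundances homoskedastic on the log scale,
#' and a planted multiplicative effect of size \code{fc} (random sign) on
#' \code{n_effect} randomly chosen species in the second group. No QC
#' injections, drift or censoring: the benchmark isolates the
#' transformation/weighting/moderation/q-value chain.
#'
#' @param n_species total species
#' @param n_effect species carrying the planted effect
#' @param fc fold change of the planted effect (> 1)
#' @param n_per_group replicates per group
#' @param noise_cv lognormal coefficient of variation
#' @param seed random seed
#' @return list with \code{study} (a \linkS4class{LipidStudy}) and
#'   \code{truth} (data.frame species, is_null, true_log2fc)
#' @export
generateTwoGroupStudy <- function(n_species = 2000L, n_effect = 200L,
                                  fc = 2, n_per_group = 3L,
                                  noise_cv = 0.15, seed = 1L) {
  stopifnot(n_effect <= n_species, fc > 0, n_per_group >= 2L)
  set.seed(seed)
  combos <- expand.grid(D = 0:6, C = 20:79, cls = LIPID_CLASSES,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos <- combos[combos$D <= combos$C, ]
  if (n_species > nrow(combos)) stop("n_species too large for the name space")
  combos <- combos[seq_len(n_species), ]
  species <- sprintf("%s %d:%d", combos$cls, combos$C, combos$D)
  base <- exp(stats::rnorm(n_species, log(10), 1.2))
  eff_idx <- sample.int(n_species, n_effect)
  sgn <- sample(c(-1, 1), n_effect, replace = TRUE)
  lfc <- numeric(n_species)
  lfc[eff_idx] <- sgn * log2(fc)
  groups <- c("WT", "mut")
  sm <- data.frame(
    sample_id = sprintf("%s_r%d", rep(groups, each = n_per_group),
                        rep(seq_len(n_per_group), 2)),
    genotype = rep(groups, each = n_per_group),
    treatment = "+N", replicate = rep(seq_len(n_per_group), 2),
    is_qc = FALSE, dry_weight_mg = 1,
    run_order = seq_len(2 * n_per_group), stringsAsFactors = FALSE)
  sdlog <- sqrt(log(1 + noise_cv^2))
  amounts <- vapply(seq_len(nrow(sm)), function(s) {
    mu <- base * if (sm$genotype[s] == "mut") 2^lfc else 1
    mu * exp(stats::rnorm(n_species, 0, sdlog))
  }, numeric(n_species))
  dimnames(amounts) <- list(species, sm$sample_id)
  list(study = LipidStudy(amounts, sm),
       truth = data.frame(species = species, is_null = lfc == 0,
                          true_log2fc = lfc, stringsAsFactors = FALSE))
}

#' Generate synthetic MALDI-MSI pixel spectra
#'
#' Places each configured lipid's true intensity field (uniform or a
#' linear x-gradient) on a leaf-shaped elliptical tissue mask over an
#' \code{nx} by \code{ny} raster, adds Poisson counting noise, and emits
#' centroided peaks at the configured m/z values with a small mass jitter.
#' Off-tissue pixels carry no peaks. Lipids whose m/z values lie closer
#' than twice the extraction tolerance are flagged in the returned truth.
#'
#' @param nx,ny raster dimensions
#' @param lipids data.frame with columns \code{mz}, \code{pattern}
#'   (\code{"uniform"} or \code{"gradient"}) and \code{level} (mean
#'   intensity on tissue)
#' @param mz_jitter SD of the mass error applied to each peak (Da)
#' @param noise use Poisson counting noise (\code{TRUE}) or emit exact
#'   levels
#' @param tol extraction tolerance used only for the overlap warning
#' @param seed random seed
#' @return list with \code{pixels} (long data.frame x, y, mz, intensity),
#'   and \code{truth} (mask, per-lipid true fields, warnings)
#' @export
generateMSI <- function(nx = 20L, ny = 20L,
                        lipids = data.frame(
                          mz = c(758.57, 786.60),
                          pattern = c("uniform", "gradient"),
                          level = c(100, 100)),
                        mz_jitter = 0.002, noise = TRUE, tol = 0.01,
                        seed = 1L) {
  stopifnot(nx > 0L, ny > 0L, nrow(lipids) >= 1L)
  set.seed(seed)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  mask <- outer(seq_len(nx), seq_len(ny), function(i, j)
    ((i - cx) / (0.45 * nx))^2 + ((j - cy) / (0.35 * ny))^2 <= 1)
  if (!any(mask)) stop("empty tissue mask: raster too small")
  warnings <- character()
  if (nrow(lipids) > 1L) {
    dd <- abs(outer(lipids$mz, lipids$mz, "-"))
    if (any(dd[upper.tri(dd)] < 2 * tol))
      warnings <- c(warnings, "lipid m/z values closer than 2x tolerance")
  }
  fields <- list()
  rows <- list()
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(lipids))) {
    f <- matrix(0, nx, ny)
    lv <- lipids$level[k]
    f[mask] <- if (lipids$pattern[k] == "gradient")
      lv * 2 * idx[, 1] / nx else lv
    obs <- f
    if (noise) obs[mask] <- stats::rpois(nrow(idx), f[mask])
    fields[[k]] <- f
    nz <- obs[mask] > 0
    if (any(nz))
      rows[[k]] <- data.frame(
        x = idx[nz, 1], y = idx[nz, 2],
        mz = lipids$mz[k] + stats::rnorm(sum(nz), 0, mz_jitter),
        intensity = obs[mask][nz])
  }
  names(fields) <- sprintf("mz_%g", lipids$mz)
  pixels <- do.call(rbind, rows)
  pixels <- pixels[order(pixels$x, pixels$y, pixels$mz), ]
  rownames(pixels) <- NULL
  list(pixels = pixels,
       truth = list(mask = mask, fields = fields, lipids = lipids,
                    warnings = warnings))
}
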