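---
title: "Models and methods behind lipidiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lipidiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidiff)
```

# Scope and data model

`lipidiff` analyses quantitative profiles of plant membrane glycerolipids:
a species × samples matrix of amounts (instrument intensity before
normalization, normalized intensity per mg dry weight after conversion)
with a sample sheet carrying genotype, nitrogen treatment, replicate, a QC
flag, dry weight and injection run order. Species are identified at the
head-group / total-carbon : total-double-bond level ("PC 34:2"); sn-position
and individual chain composition are deliberately not modelled, matching
how direct-infusion ESI-MS/MS data are reported. Eleven head-group classes
are covered: MGDG and DGDG galactolipids, the diacyl phospholipids PG, PC,
PE, PA, PS and PI, and the single-chain lysophospholipids LPC, LPE and LPG.
The central container, `LipidStudy`, extends `SummarizedExperiment`; parsed
annotations live in `rowData`, the sample sheet in `colData`.

The name parser accepts the dialects that occur in practice ("PC34:2",
"PC 34:2", "PC(34:2)", case-insensitive, "LysoPC" as an alias for LPC) and
emits a single canonical form, so downstream grouping is unambiguous.

# QC-pool normalization and analyte filtering

Recurrent injections of a pooled QC sample monitor instrument drift. The
correction model is deliberately minimal: for each analyte, QC intensity is
linearly interpolated over run order (clamped at the run ends), each
experimental intensity is divided by the interpolated QC value at its own
run position, and the result is rescaled by the analyte's grand QC median
so the units survive. Linear interpolation is the weakest assumption
consistent with using the QC analyte intensities as a drift reference;
nothing about the drift's shape beyond smoothness is assumed, and a
constant QC trace reproduces the input exactly. QC columns themselves are
passed through untouched, because the coefficient-of-variation filter that
follows must see their raw variability: an interpolating correction would
flatten the QC pool onto its own median and make every CV zero. Analytes
with an all-zero QC trace cannot be corrected; they are flagged and left
unchanged (the CV filter subsequently removes them, since their QC mean is
zero and their CV undefined).

Two filters gate analyte retention. The LOD filter removes analytes whose
mean per-mg amount across experimental samples falls below a configurable
detection limit (default 0, i.e. disabled, since no numeric LOD is
universal). The CV filter removes analytes whose QC coefficient of
variation — sample SD with the n−1 denominator divided by the mean —
strictly exceeds 0.3; a CV of exactly 0.3 is retained. The two filters
commute on the retained set, so their order is immaterial.

# The transformation and its consequences

Amounts are transformed to
$y_{ij} = \log_2\!\big((r_{ij} + \delta)/R_j \times 10^6\big)$,
with one global pseudo-amount $\delta$ — half the smallest non-zero amount
in the experimental matrix — and $R_j$ the 75th percentile
(linear-interpolation quantile) of sample $j$'s non-zero amounts. $\delta$
keeps below-detection zeros finite; computing $R_j$ over non-zero amounts
only stops censoring artifacts from dragging the quantile down. The
transform is strictly increasing within a sample and invariant to a global
rescaling of the matrix.

One consequence deserves emphasis. Dividing by a per-sample upper quartile
removes per-sample scale, exactly as library-size normalization does for
sequencing counts. A treatment that multiplies *every* species by the same
factor moves $R_j$ by that same factor and disappears from $y$: the
inferential results measure *composition*, changes relative to the bulk of
the lipidome. Effects confined to a minority of species (a lysolipid
increase, a polyunsaturated/very-long-chain decrease) are identifiable;
the uniform component of a global decrease is not, and is instead visible
in the raw-amount fold-change tables (`amountFoldChanges()`), which report
log2 ratios of per-mg cell means. Heat maps of the raw ratios and
significance masks from the relative-scale tests answer different
questions, and the package keeps both. Like any quantile-reference
normalization, the procedure assumes the species around the upper quartile
are mostly unaffected; studies in which the dominant species all shift
should interpret relative effects with care.

# Precision weights, moderation and testing

Amount data on the log scale are approximately homoskedastic at high
abundance but noisier near the detection limit. Rather than assume a
variance function, the package estimates the mean–variance trend
empirically: each species is fitted (unweighted) on the genotype ×
treatment cell-means design, the square root of the residual SD is
regressed on mean transformed abundance with a lowess smoother (span 0.5
of points), and each observation receives weight equal to the predicted
SD at its fitted value raised to the power −4. Weights are clipped to
[1e−4, 1e4] for numerical safety; with fewer than 10 species the trend is
unidentifiable and unit weights are used with a warning.

Weighted least squares on the cell-means design yields per-species cell
means, residual variances $s_g^2$ and residual df $d_g$. The design is
declared rank-deficient — with the offending cell named — if any genotype ×
treatment combination has no samples. Variances are then moderated under a
scaled inverse-chi-square prior: marginally $s_g^2 \sim s_0^2 F_{d_g,d_0}$,
and $(d_0, s_0^2)$ are estimated by matching the mean and variance of
$\log s_g^2$ to their theoretical digamma/trigamma expressions, inverting
the trigamma equation by Newton iteration. The posterior (moderated)
variance $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ is a convex
combination of observed and prior variances; when the observed
log-variances are underdispersed relative to chi-square sampling noise the
prior df is infinite and all moderated variances collapse to $s_0^2$.
Moderated t statistics use $d_0 + d_g$ degrees of freedom, capped at the
pooled residual df, since the prior cannot carry more information than the
ensemble it was estimated from. Moderation is what makes n = 2 genotypes
(WT and *atg5* in the emulated design) testable at all: their two residual
df borrow strength from the whole lipidome.

Three contrast families are tested: genotype vs reference within each
treatment, second-vs-first treatment within each genotype, and the
genotype × treatment interaction. Effects are differences of cell means on
the transformed scale. p-values become Storey q-values *within* each
family: $\pi_0(\lambda)$ is computed on the grid 0.05–0.95, smoothed by a
cubic smoothing spline (3 df) and read off at the largest $\lambda$; below
100 p-values, or when the estimate leaves (0, 1], the conservative
$\pi_0 = 1$ is used, in which case q-values coincide with
Benjamini–Hochberg adjusted p-values. The default significance rule is
q ≤ 0.1, with the stricter 0.05 available as a parameter — both levels are
conventional in this literature, and the looser one is the package's
declared calling rule.

Figure-style annotations of aggregate quantities (total lipid, class
totals, carbon:double-bond group sums) reuse the same machinery: the
aggregates are appended as pseudo-analytes, transformed, weighted and
moderated exactly like species, and all-pairwise genotype comparisons
within a treatment are encoded as compact letter displays
(insert-and-absorb algorithm; groups sharing a letter are not
significantly different). Ties in p-values are broken by species name so
output ordering is reproducible.

# Aggregation and unsaturation indices

Class totals, mol fractions, total lipid and group sums are plain
per-sample sums; conservation identities (class totals and group sums each
resum to total lipid) are enforced by construction and verified in the
tests against brute-force summation. The unsaturation index of a species
is its amount times its average number of double bonds per acyl chain
(double bonds / 2 for diacyl classes, / 1 for lyso classes); a class index
is the sum of its species' indices per sample, so it scales linearly with
amounts and is amount-weighted — a class losing its abundant unsaturated
species loses index even if the surviving species are unchanged. Replicate
class indices are compared by Welch's t-test. Indices are computed on
per-dry-weight amounts as reported, without renormalizing by class total.

# Multivariate views

PCA log10-transforms the amounts (with the same global pseudo-amount rule
to keep zeros finite), treats samples as observations, centers columns and
eigendecomposes the covariance, without unit-variance scaling — abundant
classes are allowed to dominate, which is the convention the emulated
analysis follows. Variance fractions are reported as percentages.
Heat-map row and column orders come from hierarchical clustering with
Euclidean distance and complete linkage (both configurable), the defaults
of the common heat-map tooling.

# MALDI-MSI ion images

Pixel spectra arrive as a long table (x, y, m/z, intensity) on a raster
with 100 µm pitch. An ion image sums, per pixel, all centroided peak
intensities within a *closed* ±0.01 Da window of the target m/z — the
boundary is included so the window rule is bit-exact and testable; whether
the original imaging software summed or took the maximum within the window
is not documented, and summation is adopted as the measure-like choice
(additive over disjoint windows, bounded by the total spectrum intensity).
Images of the same metabolite across samples are put on common display
bounds (global min/max; grids untouched; idempotent). Spatial uniformity —
the claim that a lipid is evenly distributed over the exposed leaf
surface — is operationalized by two statistics over a tissue mask (pixels
whose total ion current exceeds a configurable quantile, default 0.1): the
quartile coefficient of dispersion, and Moran's I under rook adjacency,
which is ≈ 0 for spatially unstructured intensity, strongly positive for
smooth gradients and −1 for a perfect checkerboard.

# The synthetic-study generator

The generator exists so that every stage — filters, error rates, power,
recovery of the effect structure — can be validated against known truth
without the original raw data. Its defaults emulate the study design it is
modelled on: nine genotypes (WT; the autophagy-blocked *atg5*, *atg7*,
*atg9*, *kin10*, *rns2;atg5*, *rns2;atg9*; the constitutive-autophagy
*rns2* and *raptor1b*) under +N and −N, three biological replicates except
two for WT and *atg5*, 120 species across the eleven classes, and seven
interleaved QC injections.

Quantitative choices, fixed once and documented here:

* **Abundance model.** Log-normal species abundances: class base amounts on
  a nmol/mg scale (MGDG 60, DGDG 30, PC 25, PE 15, PG 12, PI 8, PA 3,
  PS 2, LPC 0.4, LPE 0.25, LPG 0.12 — order-of-magnitude placeholders with
  MGDG dominant, as in leaf tissue) split within class by log-normal
  weights (SD 0.8) biased toward highly unsaturated galactolipid and PC/PE
  species and long-chain PS species, mirroring typical *Arabidopsis*
  profiles.
* **Noise.** Multiplicative log-normal observation noise with CV 0.15, a
  realistic combined biological + technical variability for replicated
  lipidomics; QC injections use CV 0.05 of technical noise around the
  drift curve.
* **Drift and censoring.** A linear multiplicative drift of ±15% across
  the run; amounts below 0.02 (per-mg scale) are reported as zero, which
  censors occasional trace lysolipid observations and yields the
  below-detection zeros the pseudo-amount δ exists for.
* **Effects.** Under −N, ordinary species are multiplied by 0.55 and
  lyso/PA species by 2.0 (the starvation response: bulk lipid loss with
  accumulation of phospholipase products). In autophagy-blocked genotypes
  under −N, polyunsaturated/very-long-chain species — the 36:6 and
  38:4–38:6 groups plus all species with ≥ 40 acyl carbons — are further
  multiplied by 0.4. The bulk 34:x galactolipids are deliberately outside
  the affected set, both because the emulated biology spares them and
  because a normalization reference only works when the dominant species
  are stable.
* **Determinism.** All randomness flows from the single config seed;
  a fixed seed reproduces the study byte-identically.

Ground truth exports the true log2 effect and null flag of every species
under every contrast the pipeline tests, plus planted LOD/CV violators and
the drift curve. A separate flat two-group generator (2,000 species, 200
planted two-fold effects with random sign, n = 3 per group, no QC/drift/
censoring) isolates the transform → weights → moderation → q-value chain
for error-rate benchmarking.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: correlated species (effects and noise
are independent across species, whereas real lipid classes co-vary through
shared synthesis), missingness that depends on the sample rather than the
amount, nonlinear or batch-structured drift, chemical noise and isobaric
overlaps, and any real quantitative calibration of the class base amounts.

# Numerical choices and degenerate inputs

Quantiles use R's default linear-interpolation definition (type 7).
Weights are clipped to [1e−4, 1e4]. The trigamma inversion runs Newton
iterations to relative tolerance 1e−10. A residual variance of zero (an
exact fit) is legal and simply shrinks fully toward the prior; estimating
the prior requires at least two positive variances. All-zero samples,
missing dry weights, empty design cells, asymmetric significance matrices,
mixed-m/z image sets and empty masks are rejected with errors naming the
offending sample, cell or input. Moran's I is reported as 0 with a
degeneracy flag when all masked intensities are equal.

# Problem sizes used in the validation suite

The test suite validates the statistical guarantees at these scales, which
are the package's documented operating points: FDR control on twenty
two-group studies of 2,000 species (200 two-fold effects, n = 3);
hyperparameter recovery on 2,000 variances at the default design's
per-lipid residual df of 32, where the moment-matching estimator and an
independent maximum-likelihood oracle agree to two significant figures (at
very small residual df the two consistent estimators can differ by a few
percent at this ensemble size); and end-to-end recovery of the planted
effect structure over fifty studies of the default design. The Welch
unsaturation-index power check uses three replicates per genotype, the
replicate count reported for the unsaturation comparisons in the emulated
study, while effect-recovery checks keep the n = 2 WT/*atg5* design.

# Known limitations

Relative, not absolute, inference after upper-quartile normalization (see
above); no isotope or internal-standard correction chemistry; no peak
picking from profile spectra or image co-registration; moderation assumes
exchangeable variances across species, which strong class structure can
violate; and the q-value smoother needs on the order of a hundred tests
per family to improve on the conservative π₀ = 1 fallback.
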