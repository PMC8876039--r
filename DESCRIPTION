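Package: lipidiff
Title: Differential Analysis of Quantitative Glycerolipidomics Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative shotgun lipidomics of plant membrane
    glycerolipids: lipid shorthand parsing and annotation, QC-pool drift
    normalization with limit-of-detection and coefficient-of-variation
    filtering, an upper-quartile log2 transformation with mean-variance
    precision weights, per-lipid weighted linear models with empirical-Bayes
    variance moderation and Storey q-value FDR control over genotype,
    treatment and interaction contrasts, head-group class and chain-length
    aggregation with unsaturation indices, principal component analysis and
    heat-map clustering, and extraction of MALDI mass-spectrometry-imaging
    ion images on a fixed raster. A synthetic-study generator with exported
    ground truth supports end-to-end validation of error-rate control and
    effect recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aggregate.R'
    'annotation.R'
    'transform.R'
    'diffstats.R'
    'io.R'
    'msi.R'
    'multivariate.R'
    'synthetic.R'
    'pipeline.R'
    'preprocess.R'
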