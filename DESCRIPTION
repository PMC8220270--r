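Package: alloaxis
Title: Ontogenetic and Evolutionary Multivariate Allometry of Limb Skeletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies multivariate allometry of limb bones from ontogenetic
    series and from species means across a phylogeny, and tests whether the
    major axis of embryonic bone growth is aligned with the major axis of
    evolutionary diversification. Provides measurement-table containers built
    on SummarizedExperiment, iterative-PCA imputation of missing bone lengths,
    bivariate log-log allometry with ANCOVA/MANCOVA species tests, per-species
    and common (pooled within-species) allometric vectors with angle
    statistics, an allometric space ordination, bootstrap tests against
    multivariate isometry and against a shared-allometry null, phylogenetic
    PCA per clade with a standard-PCA sensitivity variant, alignment tests
    between ontogenetic and evolutionary axes with rotated-dataset bootstrap
    nulls, and seeded simulators for ontogenetic series, pure-birth trees and
    Brownian-motion trait evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils-linalg.R'
    'AllClasses.R'
    'AllGenerics.R'
    'measurements.R'
    'trees.R'
    'multivariate.R'
    'phylo.R'
    'alignment.R'
    'alloaxis-package.R'
    'bivariate.R'
    'impute.R'
    'simulate.R'
    'pipeline.R'
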