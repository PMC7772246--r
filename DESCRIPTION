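Package: abilitytraits
Title: Latent Ability Traits, Brain-Feature Ensembles and Twin Heritability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives latent ability traits from toolbox-style score batteries by
    maximum-likelihood factor analysis with Horn's parallel analysis and varimax
    rotation, transfers spherical Gaussian-mixture clusters of subjects across
    cohorts, identifies brain-connectivity predictors of traits with a resampled
    L1-regression ensemble and prevalence-based stability selection, annotates
    independent components against canonical network templates, and estimates
    ACE variance components (broad-sense heritability) from twin and sibling
    pairs via Falconer's method. Ships a synthetic-cohort generator with planted
    ground truth so every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, glmnet, jsonlite
Suggests: testthat (>= 3.0.0), mclust, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
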