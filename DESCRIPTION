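Package: pedblup
Title: Pedigree-Based Threshold-Model BLUP for Familial Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian liability-threshold animal model for binary disease
    status in multi-generation family pedigrees. Builds the additive
    (numerator) relationship matrix and its sparse inverse from pedigree
    records, sets up Henderson's mixed-model equations for configurable
    fixed/random effect structures, estimates variance components and
    heritability (liability and observed scale) by Gibbs sampling with
    latent-liability augmentation and parameter-expanded inverse-gamma
    priors, and derives per-individual estimated genetic values (EGVs),
    parental-mean risk predictions, ROC discrimination and family-level
    prevalence summaries. Includes a synthetic pedigree/phenotype
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
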