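Package: tcrfate
Title: Biophysical TCR Sequence Scoring of T Cell Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts paired alpha-beta T cell receptor (TCR) sequences into
    biophysical feature vectors (positional Atchley factors, CDR composition,
    loop lengths, adjacent-residue interactions) and links them to T cell
    fate. Provides regularized canonical correlation analysis with
    permutation nulls, ridge-logistic TCR scoring functions with train-set
    standardization and single-chain variants, TCR-twin concordance testing
    with an exact log-space binomial tail, donor random-intercept association
    models, random-effects meta-analysis with a local false sign rate, and
    negative-binomial background normalization of multiplexed pMHC-Dextramer
    counts. A synthetic multi-donor repertoire generator with known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    lme4,
    metafor,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
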