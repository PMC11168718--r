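Package: latentlink
Title: Generalizability of Latent Brain-Behavior Associations from CCA and PLS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Runs canonical correlation analysis (CCA) and partial least
    squares correlation (PLS) side by side on a brain matrix and a behavior
    matrix, and assesses the generalizability of the latent variables they
    extract: sum-of-squares permutation significance, split-half
    reproducibility of loadings, train-test reliability of singular values,
    bootstrap stability of individual loading elements, and between-method
    similarity. Includes nuisance-covariate residualization, rank (Spearman)
    standardization, cross-product matrix construction, and a synthetic-data
    generator that plants known latent structure in paired blocks with
    zero-inflated ordinal or Gaussian behavioral marginals, correlated
    within-block noise, and site/scanner/age/sex/head-size covariate effects,
    so every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
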