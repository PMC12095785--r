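Package: gradlink
Title: Linking Regional Gene Expression to Learning-Dependent Changes in
    Cortical Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking node-level cortical gene expression to
    learning-dependent changes in microstructure and functional-connectivity
    gradients. Builds microstructure profile covariance (MPC) and functional
    connectivity (FC) matrices, embeds them with diffusion maps, aligns
    embeddings by Procrustes rotation, and quantifies within- and
    between-network dispersion in gradient space. Tests dispersion-behavior
    coupling with permutation nulls and leave-one-out cross-validation, and
    associates gene expression with gradient-change maps via partial least
    squares regression with permutation significance, Procrustes-corrected
    bootstrap z-weights, FDR inverse quantile transformation, spatially
    constrained surrogate maps, and hypergeometric gene-set enrichment.
    Includes a synthetic-data generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
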