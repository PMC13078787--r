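Package: stoichiomap
Title: Stoichiometry Conservation Architecture from Spectra-Omics Correspondence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links dimension-reduced single-cell Raman spectra to
    condition-dependent omics profiles and extracts the global
    stoichiometry-conservation architecture of gene expression. Provides a
    synthetic-data generator with planted stoichiometrically conserved groups
    (SCGs), Raman spectral preprocessing (background subtraction, cropping,
    Savitzky-Golay smoothing, standardization), linear discriminant analysis of
    spectra by condition, ordinary-least-squares spectra-to-proteome regression
    with leave-one-out cross-validation and a permutation test, cosine-similarity
    network analysis (SCG extraction, degree centrality, expression generality,
    Laplacian-eigenmap embeddings), comparison of the embedding- and
    regression-based proteome structures through an orthogonal alignment matrix,
    and rank-based association tests between centrality and gene annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
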