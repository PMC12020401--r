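Package: cranioshape
Title: Region-Disentangled Latent Shape Analysis of Corresponded Head Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical shape analysis of triangle head meshes in dense point
    correspondence with a shared template, aimed at objective assessment of
    craniofacial surgical outcomes. Provides synthetic corresponded-mesh
    populations with region-specific class signatures and simulated surgery,
    spectral (Laplacian eigenbasis) mesh interpolation for data augmentation,
    a toy-scale region-disentangled variational autoencoder whose latent
    subsets control individual anatomic subunits, per-class Gaussian latent
    models with quadratic discriminant classification and linear discriminant
    2D manifold visualization, and a Mahalanobis-based regional outcome
    metric quantifying how far and how correctly surgery moved each anatomic
    region toward the healthy population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
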