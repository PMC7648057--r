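Package: perturbDGM
Title: Deep Generative Models for Perturbation Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational autoencoders for L1000-style perturbation signature
    z-score profiles, including a supervised vector-quantized variational
    autoencoder (S-VQ-VAE) that learns one codebook embedding per perturbagen
    class. Provides dataset assembly and filtering for perturbation compendia,
    a synthetic-data generator with planted class structure and planted
    drug/knockdown correspondence, latent-representation extraction and
    signature-node discovery, class-conditional generation, a mixing score for
    comparing real and generated data under hierarchical clustering, nearest
    neighbour perturbagen-class graphs with Louvain communities, a
    cross-validated class-prediction harness, and correlation-based
    drug-target retrieval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
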