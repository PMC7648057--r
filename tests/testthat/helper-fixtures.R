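# Shared fixtures. Trained models are expensive, so they are memoized for
# the duration of the test session and shared across test files.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# 2000-sample synthetic dataset (8 classes x 250) used for VAE experiments
fixtureSim <- function() .memo("sim", simulateDataset(
  syntheticConfig(samplesPerClass = 250L, seed = 101L)))

# 400-sample synthetic dataset (8 x 50) used for S-VQ-VAE experiments
fixtureSimSmall <- function() .memo("simSmall", simulateDataset(
  syntheticConfig(seed = 102L)))

fixtureVAE <- function() .memo("vae", trainVAE(
  fixtureSim()$data, vaeConfig(epochs = 200L, seed = 7L)))

fixtureSVQVAE <- function() .memo("svq", trainSVQVAE(
  fixtureSimSmall()$data,
  svqvaeConfig(epochs = 800L, learningRate = 3e-3, beta = 1, seed = 7L,
               codebookInit = "classmean")))

# tiny hand-built expression container: 3 samples x 4 genes
toyPE <- function(values = NULL) {
  m <- if (is.null(values))
    matrix(c(1, -2, 3, 0.5, 2, -1, 0, 4, -3, 1, 1, -1), nrow = 3,
           byrow = TRUE)
  else values
  dimnames(m) <- list(paste0("s", seq_len(nrow(m))),
                      paste0("g", seq_len(ncol(m))))
  meta <- data.frame(perturbagen_id = paste0("p", seq_len(nrow(m))),
                     pert_type = "small_molecule", cell_line = "A375",
                     row.names = rownames(m), stringsAsFactors = FALSE)
  PerturbationExperiment(m, meta)
}

# expression container with arbitrary metadata columns
metaPE <- function(n, perturbagen, pertType, cellLine, pcl = NULL,
                   target = NULL, nGenes = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * nGenes), nrow = n,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              paste0("g", seq_len(nGenes))))
  meta <- data.frame(perturbagen_id = rep_len(perturbagen, n),
                     pert_type = rep_len(pertType, n),
                     cell_line = rep_len(cellLine, n),
                     row.names = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(pcl)) meta$pcl_label <- rep_len(pcl, n)
  if (!is.null(target)) meta$target_gene <- rep_len(target, n)
  PerturbationExperiment(m, meta)
}

# a VAE model whose weights are all zero (biases too), for closed-form checks
zeroVAE <- function(layerSizes = c(4L, 3L), inputDim = 5L, muBias = 0,
                    lvBias = 0) {
  cfg <- vaeConfig(layerSizes = layerSizes, inputDim = inputDim,
                   epochs = 1L, batchSize = 2L)
  params <- perturbDGM:::.vaeInit(cfg)
  for (nm in names(params)) params[[nm]][] <- 0
  params[["mu.b"]][] <- muBias
  params[["lv.b"]][] <- lvBias
  new("VAEModel", params = params, config = unclass(cfg),
      trainingLog = data.frame(), signature = integer(0),
      geneIds = paste0("g", seq_len(inputDim)))
}

# small randomly initialized S-VQ-VAE wrapper around a given codebook
toySVQVAE <- function(E, inputDim = 6L, hidden = 4L, seed = 2L,
                      beta = 0.25, gamma = 0.1) {
  cfg <- svqvaeConfig(hiddenSizes = hidden, embeddingDim = ncol(E),
                      inputDim = inputDim, beta = beta, gamma = gamma,
                      seed = seed)
  params <- perturbDGM:::.svqInit(cfg)
  labs <- rownames(E)
  if (is.null(labs)) labs <- paste0("class", seq_len(nrow(E)))
  rownames(E) <- labs
  new("SVQVAEModel", params = params, codebook = E, classLabels = labs,
      classCounts = rep(1L, nrow(E)), latentVar = E * 0,
      config = unclass(cfg), trainingLog = data.frame(),
      geneIds = paste0("g", seq_len(inputDim)))
}

# brute-force mixing score: per-cluster majority count
bruteMixing <- function(labels, clusters) {
  tot <- 0
  for (cl in unique(clusters)) {
    sub <- labels[clusters == cl]
    cats <- unique(labels)
    tot <- tot + max(sum(sub == cats[1]), sum(sub == cats[2]))
  }
  tot / length(labels)
}
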