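#' Configuration for the synthetic L1000-like generator
#'
#' The generator plants a low-dimensional latent class structure: each
#' perturbagen class has a latent centroid, samples scatter around it in
#' latent space, and a fixed random linear decoder maps latents to gene
#' space. Gene-level noise is added and the result is squashed into the
#' z-score range by an affine tanh map (so clipping never piles mass on the
#' boundary). A fraction of drug classes can be given a "knockdown twin"
#' class sharing (up to a small shift) the same latent centroid, planting a
#' drug/target correspondence for retrieval benchmarks.
#'
#' A single `noiseSd` knob controls the within-class latent scatter, the
#' gene-level noise, and the twin centroid shift (half `noiseSd`), so
#' `noiseSd = 0` gives identical within-class profiles and perfectly
#' correlated twins.
#'
#' @param nGenes number of genes (default 100).
#' @param nLatentTrue true latent dimension (default 10).
#' @param nClasses number of perturbagen classes (default 8).
#' @param samplesPerClass samples per class (default 50).
#' @param noiseSd noise standard deviation (default 0.3, latent units).
#' @param clipRange ordered pair, the target z-score range.
#' @param seed integer seed; generation is reproducible.
#' @param targetLinkFraction fraction of drug classes given a knockdown twin
#'   (default 0.5).
#' @param classPrior `"uniform"` (equal class sizes) or `"skewed"`
#'   (multinomial with probabilities proportional to 1/rank, mimicking
#'   unevenly distributed classes).
#' @param centroidScale sd of latent centroid coordinates (default 2).
#' @param squashScale divisor inside the tanh squash (default 3).
#' @return list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(nGenes = 100L, nLatentTrue = 10L, nClasses = 8L,
                            samplesPerClass = 50L, noiseSd = 0.3,
                            clipRange = c(-10, 10), seed = 1L,
                            targetLinkFraction = 0.5,
                            classPrior = c("uniform", "skewed"),
                            centroidScale = 2, squashScale = 3) {
  classPrior <- match.arg(classPrior)
  stopifnot(nLatentTrue <= nGenes, samplesPerClass >= 2, noiseSd >= 0,
            clipRange[1] < clipRange[2],
            targetLinkFraction >= 0, targetLinkFraction <= 1)
  structure(list(nGenes = as.integer(nGenes),
                 nLatentTrue = as.integer(nLatentTrue),
                 nClasses = as.integer(nClasses),
                 samplesPerClass = as.integer(samplesPerClass),
                 noiseSd = noiseSd, clipRange = as.numeric(clipRange),
                 seed = as.integer(seed),
                 targetLinkFraction = targetLinkFraction,
                 classPrior = classPrior, centroidScale = centroidScale,
                 squashScale = squashScale),
            class = "syntheticConfig")
}

.squash <- function(raw, cfg) {
  half <- diff(cfg$clipRange) / 2
  mid <- mean(cfg$clipRange)
  mid + half * tanh(raw / cfg$squashScale)
}

.classSizes <- function(cfg) {
  n <- cfg$nClasses * cfg$samplesPerClass
  if (cfg$classPrior == "uniform")
    return(rep(cfg$samplesPerClass, cfg$nClasses))
  p <- (1 / seq_len(cfg$nClasses)); p <- p / sum(p)
  sz <- as.integer(stats::rmultinom(1, n, p))
  pmax(sz, 2L)  # every class keeps at least two samples
}

# decode latent rows (n x nLatentTrue) through W with gene noise and squash
.decodeLatent <- function(lat, W, cfg, noise = TRUE) {
  raw <- lat %*% t(W)
  if (noise && cfg$noiseSd > 0)
    raw <- raw + matrix(stats::rnorm(length(raw), 0, cfg$noiseSd),
                        nrow = nrow(raw))
  .squash(raw, cfg)
}

.simulateClasses <- function(cfg, centroids, W, labels, pertType,
                             perturbagens, targetGenes = NULL,
                             idPrefix = "S") {
  sizes <- if (cfg$classPrior == "uniform")
    rep(cfg$samplesPerClass, length(labels))
  else .classSizes(cfg)[seq_along(labels)]
  rows <- vector("list", length(labels))
  for (ci in seq_along(labels)) {
    n <- sizes[ci]
    eps <- matrix(stats::rnorm(n * cfg$nLatentTrue, 0, cfg$noiseSd), nrow = n)
    lat <- sweep(eps, 2, centroids[ci, ], "+")
    rows[[ci]] <- .decodeLatent(lat, W, cfg)
  }
  mat <- do.call(rbind, rows)
  idx <- rep(seq_along(labels), sizes)
  meta <- data.frame(
    perturbagen_id = perturbagens[idx],
    pert_type = pertType,
    cell_line = "CL1",
    pcl_label = if (pertType == "small_molecule") labels[idx]
                else NA_character_,
    target_gene = if (is.null(targetGenes)) NA_character_
                  else targetGenes[idx],
    stringsAsFactors = FALSE)
  rownames(meta) <- sprintf("%s%04d", idPrefix, seq_len(nrow(mat)))
  rownames(mat) <- rownames(meta)
  colnames(mat) <- sprintf("g%03d", seq_len(cfg$nGenes))
  list(mat = mat, meta = meta, classOf = labels[idx])
}

#' Simulate an L1000-like dataset with planted class structure
#'
#' Draws one latent centroid per class, scatters samples around it, decodes
#' through a fixed random linear map, adds gene noise and squashes into the
#' configured range. Returns the dataset together with the generating ground
#' truth (centroids, decoder, per-sample class).
#'
#' @param cfg A [syntheticConfig()].
#' @return list with elements `data` (a [PerturbationExperiment-class]) and
#'   `truth` (list: `centroids`, `W`, `classOf`, `decodedCentroids`).
#' @export
simulateDataset <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$seed)
  W <- matrix(stats::rnorm(cfg$nGenes * cfg$nLatentTrue,
                           0, 1 / sqrt(cfg$nLatentTrue)),
              nrow = cfg$nGenes)
  centroids <- matrix(stats::rnorm(cfg$nClasses * cfg$nLatentTrue,
                                   0, cfg$centroidScale),
                      nrow = cfg$nClasses)
  labels <- sprintf("PCL_%02d", seq_len(cfg$nClasses))
  drugs <- sprintf("drug_%02d", seq_len(cfg$nClasses))
  sim <- .simulateClasses(cfg, centroids, W, labels, "small_molecule", drugs)
  pe <- PerturbationExperiment(sim$mat, sim$meta,
                               geneIds = colnames(sim$mat),
                               zrange = cfg$clipRange)
  truth <- list(centroids = centroids, W = W, classOf = sim$classOf,
                decodedCentroids = .squash(centroids %*% t(W), cfg),
                config = cfg)
  list(data = pe, truth = truth)
}

#' Simulate a planted drug-target retrieval benchmark
#'
#' Generates a small-molecule dataset (one drug per class) and a knockdown
#' dataset in which each *linked* drug class has a twin knockdown class whose
#' latent centroid equals the drug centroid plus a small shift
#' (sd = `noiseSd / 2`); additional unlinked knockdown classes act as
#' distractor genes. The truth table lists each linked drug with the gene
#' symbol of its twin knockdown.
#'
#' @param cfg A [syntheticConfig()] with `targetLinkFraction > 0`.
#' @param nDistractors number of unlinked knockdown classes (default 20).
#' @return list with `smp`, `gp` ([PerturbationExperiment-class]) and
#'   `truth` (data.frame `drug_id`, `target_gene`).
#' @export
simulateDrugTargetBenchmark <- function(cfg = syntheticConfig(),
                                        nDistractors = 20L) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  if (cfg$targetLinkFraction <= 0)
    stop("targetLinkFraction must be > 0 to plant drug-target links")
  set.seed(cfg$seed)
  W <- matrix(stats::rnorm(cfg$nGenes * cfg$nLatentTrue,
                           0, 1 / sqrt(cfg$nLatentTrue)),
              nrow = cfg$nGenes)
  centroids <- matrix(stats::rnorm(cfg$nClasses * cfg$nLatentTrue,
                                   0, cfg$centroidScale),
                      nrow = cfg$nClasses)
  labels <- sprintf("PCL_%02d", seq_len(cfg$nClasses))
  drugs <- sprintf("drug_%02d", seq_len(cfg$nClasses))
  smpSim <- .simulateClasses(cfg, centroids, W, labels,
                             "small_molecule", drugs, idPrefix = "SM")
  nLinked <- max(1L, round(cfg$targetLinkFraction * cfg$nClasses))
  linked <- seq_len(nLinked)
  twinC <- centroids[linked, , drop = FALSE] +
    matrix(stats::rnorm(nLinked * cfg$nLatentTrue, 0, cfg$noiseSd / 2),
           nrow = nLinked)
  distC <- matrix(stats::rnorm(nDistractors * cfg$nLatentTrue,
                               0, cfg$centroidScale),
                  nrow = nDistractors)
  gpC <- rbind(twinC, distC)
  gpGenes <- c(sprintf("TGT%02d", linked),
               sprintf("DIST%02d", seq_len(nDistractors)))
  gpSim <- .simulateClasses(cfg, gpC, W,
                            paste0("KD_", gpGenes), "knockdown",
                            paste0("shRNA_", gpGenes),
                            targetGenes = gpGenes, idPrefix = "KD")
  smp <- PerturbationExperiment(smpSim$mat, smpSim$meta,
                                geneIds = colnames(smpSim$mat),
                                zrange = cfg$clipRange)
  gp <- PerturbationExperiment(gpSim$mat, gpSim$meta,
                               geneIds = colnames(gpSim$mat),
                               zrange = cfg$clipRange)
  truth <- data.frame(drug_id = drugs[linked],
                      target_gene = sprintf("TGT%02d", linked),
                      stringsAsFactors = FALSE)
  list(smp = smp, gp = gp, truth = truth)
}
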