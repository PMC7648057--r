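#' VAE configuration
#'
#' Architecture and training hyperparameters for the variational autoencoder.
#' `layerSizes` gives the encoder hidden-layer widths; the last entry is the
#' top hidden layer, i.e. the latent dimension. Hidden layers use the tanh
#' activation; the Gaussian heads (mean and log-variance) are affine so the
#' latent space is unbounded, matching the standard-normal prior. The decoder
#' mirrors the encoder and its output is squashed by tanh and rescaled by
#' `outputScale` so reconstructions stay inside the z-score range.
#'
#' The default architecture is desk-scale; `preset = "paper"` selects the
#' full-scale L1000 setting (978-1000-1000-100, 300 epochs, batch 512,
#' learning rate 1e-3).
#'
#' @param layerSizes integer vector of encoder hidden widths (last = latent).
#' @param inputDim input dimension; inferred from data when NULL.
#' @param outputScale half-range of the decoder output (default 10).
#' @param epochs,batchSize,learningRate Adam training settings.
#' @param seed integer; controls initialization, split and minibatching.
#' @param trainFraction fraction of samples used for training (default 9/10).
#' @param preset optional `"paper"` to load the full-scale setting.
#' @return list of class `"vaeConfig"`.
#' @export
vaeConfig <- function(layerSizes = c(64L, 64L, 16L), inputDim = NULL,
                      outputScale = 10, epochs = 100L, batchSize = 64L,
                      learningRate = 1e-3, seed = 1L, trainFraction = 0.9,
                      preset = NULL) {
  if (!is.null(preset) && preset == "paper") {
    layerSizes <- c(1000L, 1000L, 100L); inputDim <- 978L
    epochs <- 300L; batchSize <- 512L; learningRate <- 1e-3
  }
  stopifnot(length(layerSizes) >= 1, all(layerSizes >= 1), outputScale > 0,
            trainFraction > 0, trainFraction <= 1)
  structure(list(layerSizes = as.integer(layerSizes),
                 inputDim = if (is.null(inputDim)) NULL else
                   as.integer(inputDim),
                 outputScale = outputScale, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, seed = as.integer(seed),
                 trainFraction = trainFraction),
            class = "vaeConfig")
}

.vaeDims <- function(cfg) {
  L <- length(cfg$layerSizes)
  list(hidden = if (L > 1) cfg$layerSizes[-L] else integer(0),
       latent = cfg$layerSizes[L])
}

.vaeInit <- function(cfg) {
  d <- .vaeDims(cfg)
  set.seed(cfg$seed)
  params <- list()
  sizes <- c(cfg$inputDim, d$hidden)
  for (i in seq_along(d$hidden)) {
    ly <- .initLayer(sizes[i], sizes[i + 1])
    params[[paste0("enc", i, ".W")]] <- ly$W
    params[[paste0("enc", i, ".b")]] <- ly$b
  }
  top <- if (length(d$hidden)) d$hidden[length(d$hidden)] else cfg$inputDim
  for (nm in c("mu", "lv")) {
    ly <- .initLayer(top, d$latent)
    params[[paste0(nm, ".W")]] <- ly$W
    params[[paste0(nm, ".b")]] <- ly$b
  }
  dsizes <- c(d$latent, rev(d$hidden))
  for (i in seq_along(rev(d$hidden))) {
    ly <- .initLayer(dsizes[i], dsizes[i + 1])
    params[[paste0("dec", i, ".W")]] <- ly$W
    params[[paste0("dec", i, ".b")]] <- ly$b
  }
  ly <- .initLayer(dsizes[length(dsizes)], cfg$inputDim)
  params[["out.W"]] <- ly$W
  params[["out.b"]] <- ly$b
  params
}

.vaeEncodeForward <- function(params, X, cfg) {
  nh <- length(.vaeDims(cfg)$hidden)
  acts <- .tanhStack(X, params, "enc", nh)
  A <- acts[[nh + 1L]]
  mu <- .affine(A, params, "mu")
  lv <- pmin(pmax(.affine(A, params, "lv"), -15), 15)
  list(acts = acts, mu = mu, lv = lv, sigma2 = exp(lv))
}

.vaeDecodeForward <- function(params, Z, cfg) {
  nh <- length(.vaeDims(cfg)$hidden)
  acts <- .tanhStack(Z, params, "dec", nh)
  U <- .affine(acts[[nh + 1L]], params, "out")
  tU <- tanh(U)
  list(acts = acts, tU = tU, Xhat = cfg$outputScale * tU)
}

# loss and hand-derived gradients for one minibatch; eps is the pre-drawn
# N(0,1) noise used by the reparameterization trick
.vaeLossGrad <- function(params, X, eps, cfg, wantGrads = TRUE) {
  n <- nrow(X)
  enc <- .vaeEncodeForward(params, X, cfg)
  sd_ <- sqrt(enc$sigma2)
  Z <- enc$mu + sd_ * eps
  dec <- .vaeDecodeForward(params, Z, cfg)
  resid <- dec$Xhat - X
  recon <- mean(resid^2)
  kl <- sum(0.5 * (enc$mu^2 + enc$sigma2 - 1 - enc$lv)) / n
  out <- list(reconstruction = recon, kl = kl, total = recon + kl)
  if (!wantGrads) return(out)
  nh <- length(.vaeDims(cfg)$hidden)
  grads <- list()
  dXhat <- 2 * resid / length(resid)
  dU <- dXhat * cfg$outputScale * (1 - dec$tU^2)
  grads[["out.W"]] <- crossprod(dec$acts[[nh + 1L]], dU)
  grads[["out.b"]] <- colSums(dU)
  G <- dU %*% t(params[["out.W"]])
  bk <- .tanhStackBackward(G, dec$acts, params, "dec", nh, grads)
  grads <- bk$grads
  dZ <- bk$dInput
  dMu <- dZ + enc$mu / n
  dLv <- dZ * 0.5 * sd_ * eps + 0.5 * (enc$sigma2 - 1) / n
  A <- enc$acts[[nh + 1L]]
  grads[["mu.W"]] <- crossprod(A, dMu)
  grads[["mu.b"]] <- colSums(dMu)
  grads[["lv.W"]] <- crossprod(A, dLv)
  grads[["lv.b"]] <- colSums(dLv)
  G <- dMu %*% t(params[["mu.W"]]) + dLv %*% t(params[["lv.W"]])
  bk <- .tanhStackBackward(G, enc$acts, params, "enc", nh, grads)
  out$grads <- bk$grads
  out
}

.asSampleMatrix <- function(x) {
  if (is(x, "PerturbationExperiment")) sampleMatrix(x)
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1L)
}

#' Train a variational autoencoder on expression profiles
#'
#' Splits the data into train/validation by a seeded random permutation,
#' then optimizes reconstruction MSE plus the closed-form Gaussian KL
#' divergence with the Adam optimizer over shuffled minibatches. The run is
#' reproducible under a fixed seed (single-threaded R arithmetic).
#'
#' @param data A [PerturbationExperiment-class] or samples x genes matrix.
#' @param cfg A [vaeConfig()].
#' @param verbose print per-epoch losses every 20 epochs.
#' @return A [VAEModel-class]; `trainingLog(model)` has per-epoch
#'   `train_total`, `train_recon`, `train_kl`, `val_total`, `val_recon`,
#'   `val_kl`.
#' @export
trainVAE <- function(data, cfg = vaeConfig(), verbose = FALSE) {
  X <- .asSampleMatrix(data)
  if (is.null(cfg$inputDim)) cfg$inputDim <- ncol(X)
  if (ncol(X) != cfg$inputDim)
    stop("data has ", ncol(X), " genes but config expects ", cfg$inputDim)
  if (nrow(X) < cfg$batchSize)
    stop("need at least batchSize (", cfg$batchSize, ") samples")
  sp <- .splitIdx(nrow(X), cfg$trainFraction, cfg$seed)
  Xtr <- X[sp$train, , drop = FALSE]
  Xval <- X[sp$val, , drop = FALSE]
  params <- .vaeInit(cfg)
  st <- .adamInit(params)
  latent <- .vaeDims(cfg)$latent
  log <- vector("list", cfg$epochs)
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1L, nrow(Xtr), by = cfg$batchSize)
    epLoss <- c(total = 0, recon = 0, kl = 0); nb <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, nrow(Xtr))]
      B <- Xtr[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * latent), nrow = length(idx))
      lg <- .vaeLossGrad(params, B, eps, cfg)
      if (!is.finite(lg$total))
        stop("training diverged (non-finite loss) at epoch ", ep)
      up <- .adamStep(params, lg$grads, st, cfg$learningRate)
      params <- up$params; st <- up$state
      epLoss <- epLoss + c(lg$total, lg$reconstruction, lg$kl)
      nb <- nb + 1L
    }
    epLoss <- epLoss / nb
    val <- if (nrow(Xval)) {
      ev <- matrix(stats::rnorm(nrow(Xval) * latent), nrow = nrow(Xval))
      v <- .vaeLossGrad(params, Xval, ev, cfg, wantGrads = FALSE)
      c(v$total, v$reconstruction, v$kl)
    } else c(NA, NA, NA)
    log[[ep]] <- data.frame(epoch = ep, train_total = epLoss[1],
                            train_recon = epLoss[2], train_kl = epLoss[3],
                            val_total = val[1], val_recon = val[2],
                            val_kl = val[3])
    if (verbose && ep %% 20L == 0L)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, epLoss[1], val[1]))
  }
  gid <- if (is(data, "PerturbationExperiment")) geneIds(data)
         else colnames(X)
  if (is.null(gid)) gid <- paste0("gene", seq_len(ncol(X)))
  new("VAEModel", params = params, config = unclass(cfg),
      trainingLog = do.call(rbind, log), signature = integer(0),
      geneIds = gid)
}

#' Encode profiles to the Gaussian posterior parameters
#'
#' Deterministic: returns the posterior mean and diagonal variance at the top
#' hidden layer for each sample.
#'
#' @param model A [VAEModel-class].
#' @param x profile matrix (samples x genes), single profile vector, or
#'   [PerturbationExperiment-class].
#' @return list with matrices `mu` and `sigma2` (samples x latent).
#' @export
encodeSamples <- function(model, x) {
  X <- .asSampleMatrix(x)
  cfg <- model@config
  if (ncol(X) != cfg$inputDim)
    stop("profile length ", ncol(X), " does not match input dimension ",
         cfg$inputDim)
  enc <- .vaeEncodeForward(model@params, X, cfg)
  list(mu = enc$mu, sigma2 = enc$sigma2)
}

#' Reparameterized latent sample
#'
#' Draws `z = mu + sqrt(sigma2) * eps`, `eps ~ N(0, I)`.
#'
#' @param mu,sigma2 matrices (samples x latent) or vectors; `sigma2 >= 0`.
#' @param seed optional integer for reproducible draws.
#' @return matrix of latent samples.
#' @export
sampleLatent <- function(mu, sigma2, seed = NULL) {
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1L)
  if (!is.matrix(sigma2)) sigma2 <- matrix(sigma2, nrow = 1L)
  stopifnot(all(dim(mu) == dim(sigma2)), all(sigma2 >= 0))
  if (!is.null(seed)) set.seed(seed)
  mu + sqrt(sigma2) * matrix(stats::rnorm(length(mu)), nrow = nrow(mu))
}

#' Decode latent vectors to expression profiles
#'
#' Applies the decoder stack; the final layer is `outputScale * tanh(.)`, so
#' outputs always lie within the configured range.
#'
#' @param model A [VAEModel-class].
#' @param z latent matrix (samples x latent) or single vector.
#' @return matrix of decoded profiles (samples x genes).
#' @export
decodeLatent <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  cfg <- model@config
  if (ncol(z) != .vaeDims(cfg)$latent)
    stop("latent length ", ncol(z), " does not match latent dimension ",
         .vaeDims(cfg)$latent)
  dec <- .vaeDecodeForward(model@params, z, cfg)
  colnames(dec$Xhat) <- model@geneIds
  dec$Xhat
}

#' VAE loss breakdown on a batch
#'
#' Reconstruction is the mean squared error over all matrix elements; the KL
#' term is the closed-form Gaussian divergence
#' `sum_dims 0.5 (mu^2 + sigma2 - 1 - log sigma2)` averaged over the batch;
#' `total = reconstruction + kl`. By default the reconstruction is evaluated
#' at the posterior mean (deterministic); set `sample = TRUE` for the
#' stochastic training-path estimate.
#'
#' @param model A [VAEModel-class].
#' @param batch samples x genes matrix or [PerturbationExperiment-class].
#' @param sample logical; use a reparameterized draw instead of the mean.
#' @param seed seed for the draw when `sample = TRUE`.
#' @return list with `reconstruction`, `kl`, `total`.
#' @export
vaeLoss <- function(model, batch, sample = FALSE, seed = NULL) {
  X <- .asSampleMatrix(batch)
  if (!nrow(X)) stop("batch is empty")
  cfg <- model@config
  latent <- .vaeDims(cfg)$latent
  eps <- if (sample) {
    if (!is.null(seed)) set.seed(seed)
    matrix(stats::rnorm(nrow(X) * latent), nrow = nrow(X))
  } else matrix(0, nrow(X), latent)
  lg <- .vaeLossGrad(model@params, X, eps, cfg, wantGrads = FALSE)
  lg[c("reconstruction", "kl", "total")]
}

#' Analytic VAE gradients on a batch (diagnostic)
#'
#' Exposes the hand-derived backward pass so it can be checked against
#' finite differences. The reparameterization noise must be supplied to make
#' the loss a deterministic function of the parameters.
#'
#' @param model A [VAEModel-class].
#' @param batch samples x genes matrix.
#' @param eps noise matrix (samples x latent).
#' @return list with loss components and `grads` (named like the parameters).
#' @export
vaeGradients <- function(model, batch, eps) {
  .vaeLossGrad(model@params, .asSampleMatrix(batch), eps, model@config)
}

#' Generate new profiles from the prior
#'
#' Samples latent vectors from N(0, I) and decodes them, mirroring the
#' ancestral generation of new expression data.
#'
#' @param model A [VAEModel-class].
#' @param n number of samples (> 0).
#' @param seed integer seed.
#' @return A [PerturbationExperiment-class] with `pert_type = "control"` and
#'   `perturbagen_id = "generated"` placeholders.
#' @export
generateSamples <- function(model, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  latent <- .vaeDims(model@config)$latent
  Z <- matrix(stats::rnorm(n * latent), nrow = n)
  Xhat <- decodeLatent(model, Z)
  rownames(Xhat) <- sprintf("gen%05d", seq_len(n))
  meta <- data.frame(perturbagen_id = rep("generated", n),
                     pert_type = "control", cell_line = "generated",
                     row.names = rownames(Xhat), stringsAsFactors = FALSE)
  PerturbationExperiment(Xhat, meta, geneIds = model@geneIds,
                         zrange = c(-model@config$outputScale,
                                    model@config$outputScale))
}

#' Per-epoch training log of a fitted model
#' @param model A [VAEModel-class] or [SVQVAEModel-class].
#' @return data.frame of per-epoch losses.
#' @export
trainingLog <- function(model) model@trainingLog

#' Save / load a model checkpoint
#'
#' The checkpoint holds the resolved config and every parameter tensor and
#' round-trips exactly.
#'
#' @param model A [VAEModel-class] or [SVQVAEModel-class].
#' @param path file path.
#' @return `loadModel` returns the model; `saveModel` returns `path`
#'   invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)

setMethod("show", "VAEModel", function(object) {
  d <- .vaeDims(object@config)
  cat("VAEModel:", object@config$inputDim, "->",
      paste(object@config$layerSizes, collapse = "-"),
      "(latent", d$latent, ")\n")
  if (nrow(object@trainingLog)) {
    lastRow <- object@trainingLog[nrow(object@trainingLog), ]
    cat(sprintf("  trained %d epochs; final val loss %.4f (recon %.4f, kl %.4f)\n",
                nrow(object@trainingLog), lastRow$val_total,
                lastRow$val_recon, lastRow$val_kl))
  }
  if (length(object@signature))
    cat("  signature nodes:", paste(object@signature, collapse = ", "), "\n")
  invisible(NULL)
})
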