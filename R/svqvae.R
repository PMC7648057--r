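#' S-VQ-VAE configuration
#'
#' The supervised vector-quantized VAE has a tanh hidden stack, an affine
#' head producing the continuous encoding vector of dimension
#' `embeddingDim`, a codebook with one code per class, and a decoder
#' mirroring the encoder (tanh output rescaled by `outputScale`). `beta`
#' weights the commitment loss pulling encodings toward their class code;
#' `gamma` weights the divergence loss pushing encodings away from the
#' nearest wrong-class code.
#'
#' `preset = "paper"` selects the full-scale setting: a single hidden layer
#' of 1000 nodes, embedding dimension 1000, 900 epochs, batch 256, learning
#' rate 1e-4.
#'
#' @param hiddenSizes encoder hidden-layer widths (default 64).
#' @param embeddingDim dimension D of the codes (= encoder output width).
#' @param inputDim input dimension; inferred from data when NULL.
#' @param beta commitment coefficient (default 0.25).
#' @param gamma divergence coefficient (default 0.1).
#' @param outputScale half-range of decoder output (default 10).
#' @param epochs,batchSize,learningRate Adam training settings.
#' @param seed integer seed.
#' @param trainFraction training fraction; the split is stratified by class
#'   so every code sees training and (where possible) validation samples.
#' @param codebookInit `"random"` (small uniform values) or `"classmean"`
#'   (class means of the initial encodings).
#' @param preset optional `"paper"`.
#' @return list of class `"svqvaeConfig"`.
#' @export
svqvaeConfig <- function(hiddenSizes = 64L, embeddingDim = 16L,
                         inputDim = NULL, beta = 0.25, gamma = 0.1,
                         outputScale = 10, epochs = 200L, batchSize = 64L,
                         learningRate = 1e-3, seed = 1L, trainFraction = 0.9,
                         codebookInit = c("random", "classmean"),
                         preset = NULL) {
  codebookInit <- match.arg(codebookInit)
  if (!is.null(preset) && preset == "paper") {
    hiddenSizes <- 1000L; embeddingDim <- 1000L; inputDim <- 978L
    epochs <- 900L; batchSize <- 256L; learningRate <- 1e-4
  }
  stopifnot(beta >= 0, gamma >= 0, outputScale > 0, all(hiddenSizes >= 1))
  structure(list(hiddenSizes = as.integer(hiddenSizes),
                 embeddingDim = as.integer(embeddingDim),
                 inputDim = if (is.null(inputDim)) NULL else
                   as.integer(inputDim),
                 beta = beta, gamma = gamma, outputScale = outputScale,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, seed = as.integer(seed),
                 trainFraction = trainFraction, codebookInit = codebookInit),
            class = "svqvaeConfig")
}

.svqInit <- function(cfg) {
  set.seed(cfg$seed)
  params <- list()
  sizes <- c(cfg$inputDim, cfg$hiddenSizes)
  for (i in seq_along(cfg$hiddenSizes)) {
    ly <- .initLayer(sizes[i], sizes[i + 1])
    params[[paste0("enc", i, ".W")]] <- ly$W
    params[[paste0("enc", i, ".b")]] <- ly$b
  }
  ly <- .initLayer(sizes[length(sizes)], cfg$embeddingDim)
  params[["head.W"]] <- ly$W
  params[["head.b"]] <- ly$b
  dsizes <- c(cfg$embeddingDim, rev(cfg$hiddenSizes))
  for (i in seq_along(cfg$hiddenSizes)) {
    ly <- .initLayer(dsizes[i], dsizes[i + 1])
    params[[paste0("dec", i, ".W")]] <- ly$W
    params[[paste0("dec", i, ".b")]] <- ly$b
  }
  ly <- .initLayer(dsizes[length(dsizes)], cfg$inputDim)
  params[["out.W"]] <- ly$W
  params[["out.b"]] <- ly$b
  params
}

.svqEncode <- function(params, X, cfg) {
  nh <- length(cfg$hiddenSizes)
  acts <- .tanhStack(X, params, "enc", nh)
  list(acts = acts, ze = .affine(acts[[nh + 1L]], params, "head"))
}

.svqDecode <- function(params, Z, cfg) {
  nh <- length(cfg$hiddenSizes)
  acts <- .tanhStack(Z, params, "dec", nh)
  U <- .affine(acts[[nh + 1L]], params, "out")
  tU <- tanh(U)
  list(acts = acts, tU = tU, Xhat = cfg$outputScale * tU)
}

#' Nearest code in the embedding space
#'
#' Returns, for each encoding vector, the index of the Euclidean-nearest
#' codebook row; exact ties are broken by the lowest index.
#'
#' @param E codebook matrix (classes x D) or a [SVQVAEModel-class].
#' @param ze encoding vector or matrix of encoding rows.
#' @return integer vector of 1-based code indices.
#' @export
nearestEmbedding <- function(E, ze) {
  if (is(E, "SVQVAEModel")) E <- E@codebook
  if (!is.matrix(E) || nrow(E) == 0L) stop("codebook is empty")
  if (!is.matrix(ze)) ze <- matrix(ze, nrow = 1L)
  if (ncol(ze) != ncol(E))
    stop("encoding dimension ", ncol(ze), " does not match codebook width ",
         ncol(E))
  # ||ze - e||^2 = ||ze||^2 - 2 ze.e + ||e||^2; ||ze||^2 constant per row
  sc <- ze %*% t(E)
  d2 <- sweep(-2 * sc, 2, rowSums(E^2), "+")
  apply(d2, 1L, which.min)
}

.labelIdx <- function(model, y) {
  if (is.numeric(y)) {
    y <- as.integer(y)
    if (any(y < 1L | y > length(model@classLabels)))
      stop("class index out of range")
    return(y)
  }
  idx <- match(as.character(y), model@classLabels)
  if (anyNA(idx))
    stop("unknown class label(s): ",
         paste(unique(y[is.na(idx)]), collapse = ", "))
  idx
}

#' S-VQ-VAE forward pass
#'
#' In train mode the encoding vector is replaced by the code of the sample's
#' own class (`z_q = e_y`); in test mode by its Euclidean-nearest code. The
#' nearest-code index `k` is reported in both modes.
#'
#' @param model A [SVQVAEModel-class].
#' @param x profile matrix (samples x genes) or vector.
#' @param y class labels (or indices); required in train mode.
#' @param mode `"train"` or `"test"`.
#' @return list with `reconstruction` (samples x genes), `ze`, `zq`, `k`.
#' @export
svqvaeForward <- function(model, x, y = NULL, mode = c("test", "train")) {
  mode <- match.arg(mode)
  X <- .asSampleMatrix(x)
  cfg <- model@config
  if (ncol(X) != cfg$inputDim)
    stop("profile length ", ncol(X), " does not match input dimension ",
         cfg$inputDim)
  enc <- .svqEncode(model@params, X, cfg)
  k <- nearestEmbedding(model@codebook, enc$ze)
  zq <- if (mode == "train") {
    if (is.null(y)) stop("train mode requires class labels")
    model@codebook[.labelIdx(model, y), , drop = FALSE]
  } else {
    model@codebook[k, , drop = FALSE]
  }
  dec <- .svqDecode(model@params, zq, cfg)
  recon <- dec$Xhat
  colnames(recon) <- model@geneIds
  list(reconstruction = recon, ze = enc$ze, zq = zq, k = k)
}

#' Decode a quantized (or arbitrary) code to a profile
#'
#' @param model A [SVQVAEModel-class].
#' @param z code matrix (samples x D) or vector.
#' @return matrix of decoded profiles.
#' @export
decodeCode <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  out <- .svqDecode(model@params, z, model@config)$Xhat
  colnames(out) <- model@geneIds
  out
}

# loss components + straight-through gradients for one labelled minibatch.
# E enters as params[["E"]]. Per-sample squared norms are averaged over the
# batch; reconstruction is elementwise MSE.
.svqLossGrad <- function(params, X, yIdx, cfg, wantGrads = TRUE) {
  n <- nrow(X)
  E <- params[["E"]]
  enc <- .svqEncode(params, X, cfg)
  ze <- enc$ze
  k <- nearestEmbedding(E, ze)
  Ey <- E[yIdx, , drop = FALSE]
  Ek <- E[k, , drop = FALSE]
  mis <- as.numeric(k != yIdx)
  dec <- .svqDecode(params, Ey, cfg)
  resid <- dec$Xhat - X
  lr <- mean(resid^2)
  dy <- ze - Ey
  dk <- ze - Ek
  dictCore <- sum(dy^2) / n
  divCore <- sum(mis * rowSums(dk^2)) / n
  comp <- list(reconstruction = lr,
               dictionary = dictCore,
               commitment = cfg$beta * dictCore,
               misclassDictionary = divCore,
               divergence = cfg$gamma * divCore)
  comp$total <- lr + comp$dictionary + comp$commitment -
    comp$misclassDictionary - comp$divergence
  if (!wantGrads) return(c(comp, list(k = k, ze = ze)))
  nh <- length(cfg$hiddenSizes)
  grads <- list()
  dXhat <- 2 * resid / length(resid)
  dU <- dXhat * cfg$outputScale * (1 - dec$tU^2)
  grads[["out.W"]] <- crossprod(dec$acts[[nh + 1L]], dU)
  grads[["out.b"]] <- colSums(dU)
  G <- dU %*% t(params[["out.W"]])
  bk <- .tanhStackBackward(G, dec$acts, params, "dec", nh, grads)
  grads <- bk$grads
  dZq <- bk$dInput                       # recon gradient at the decoder input
  # straight-through copy plus commitment pull and divergence push
  dZe <- dZq + (2 * cfg$beta / n) * dy - (2 * cfg$gamma / n) * mis * dk
  # codebook: dictionary pulls e_y toward ze; the subtracted mis-class
  # dictionary term pushes e_k away from ze (k != y only)
  dE <- matrix(0, nrow(E), ncol(E))
  pull <- rowsum((-2 / n) * dy, yIdx)
  dE[as.integer(rownames(pull)), ] <- dE[as.integer(rownames(pull)), ] + pull
  if (any(mis > 0)) {
    sel <- mis > 0
    push <- rowsum((2 / n) * dk[sel, , drop = FALSE], k[sel])
    dE[as.integer(rownames(push)), ] <-
      dE[as.integer(rownames(push)), ] + push
  }
  grads[["E"]] <- dE
  A <- enc$acts[[nh + 1L]]
  grads[["head.W"]] <- crossprod(A, dZe)
  grads[["head.b"]] <- colSums(dZe)
  G <- dZe %*% t(params[["head.W"]])
  bk <- .tanhStackBackward(G, enc$acts, params, "enc", nh, grads)
  c(comp, list(k = k, ze = ze, grads = bk$grads))
}

#' S-VQ-VAE loss breakdown
#'
#' Components of the supervised VQ objective on a labelled batch:
#' reconstruction MSE of `decode(e_y)`, the dictionary loss
#' `||sg[z_e] - e_y||^2`, the commitment loss `beta ||z_e - sg[e_y]||^2`,
#' and the two subtracted terms gated by `I(k != y)` — the mis-class
#' dictionary loss and the divergence loss (`gamma`-scaled). Squared norms
#' are averaged over the batch. The mis-class terms vanish when every
#' sample's nearest code is its own class code.
#'
#' @param model A [SVQVAEModel-class].
#' @param x profile matrix or vector.
#' @param y class labels.
#' @return list with `reconstruction`, `dictionary`, `commitment`,
#'   `misclassDictionary`, `divergence`, `total`, and the nearest-code
#'   indices `k`.
#' @export
svqvaeLoss <- function(model, x, y) {
  X <- .asSampleMatrix(x)
  params <- c(model@params, list(E = model@codebook))
  out <- .svqLossGrad(params, X, .labelIdx(model, y), model@config,
                      wantGrads = FALSE)
  if (!is.finite(out$total)) stop("non-finite S-VQ-VAE loss")
  out[c("reconstruction", "dictionary", "commitment", "misclassDictionary",
        "divergence", "total", "k")]
}

#' Analytic S-VQ-VAE gradients (straight-through diagnostic)
#'
#' Returns the gradients used in training, with the straight-through
#' estimator across the quantization step: encoder parameters receive the
#' reconstruction gradient as if the reconstruction had been computed from
#' `z_e` shifted to `e_y`; codebook rows receive gradient only from the
#' dictionary and mis-class terms; decoder parameters only from the
#' reconstruction.
#'
#' @param model A [SVQVAEModel-class].
#' @param x profile matrix or vector.
#' @param y class labels.
#' @return list of loss components plus `grads` (including `E`).
#' @export
svqvaeGradients <- function(model, x, y) {
  X <- .asSampleMatrix(x)
  params <- c(model@params, list(E = model@codebook))
  .svqLossGrad(params, X, .labelIdx(model, y), model@config)
}

#' Train an S-VQ-VAE on class-labelled profiles
#'
#' Every sample must carry a class label (by default the `pcl_label`
#' metadata). The split is stratified by class; training minimizes the
#' supervised VQ objective with Adam, routing gradients across the
#' quantization by the straight-through estimator. The per-epoch log records
#' the loss components and the validation nearest-code label-match rate.
#'
#' @param data A [PerturbationExperiment-class] (with `pcl_label`) or a
#'   samples x genes matrix.
#' @param cfg A [svqvaeConfig()].
#' @param labels optional explicit label vector overriding `pcl_label`.
#' @param verbose print progress every 20 epochs.
#' @return A [SVQVAEModel-class].
#' @export
trainSVQVAE <- function(data, cfg = svqvaeConfig(), labels = NULL,
                        verbose = FALSE) {
  X <- .asSampleMatrix(data)
  if (is.null(labels)) {
    if (!is(data, "PerturbationExperiment") ||
        !"pcl_label" %in% colnames(sampleInfo(data)))
      stop("class labels are required (pcl_label metadata or `labels`)")
    labels <- sampleInfo(data)$pcl_label
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop("every sample must be labelled")
  classLabels <- sort(unique(labels))
  if (length(classLabels) < 2L) stop("at least two classes are required")
  yIdx <- match(labels, classLabels)
  if (is.null(cfg$inputDim)) cfg$inputDim <- ncol(X)
  params <- .svqInit(cfg)
  E <- switch(cfg$codebookInit,
    random = matrix(stats::runif(length(classLabels) * cfg$embeddingDim,
                                 -0.1, 0.1),
                    nrow = length(classLabels)),
    classmean = {
      ze0 <- .svqEncode(params, X, cfg)$ze
      t(vapply(seq_along(classLabels), function(ci)
        colMeans(ze0[yIdx == ci, , drop = FALSE]),
        numeric(cfg$embeddingDim)))
    })
  params[["E"]] <- E
  sp <- .splitIdx(nrow(X), cfg$trainFraction, cfg$seed, strata = labels)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- yIdx[sp$train]
  Xval <- X[sp$val, , drop = FALSE]; yval <- yIdx[sp$val]
  st <- .adamInit(params)
  log <- vector("list", cfg$epochs)
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1L, nrow(Xtr), by = cfg$batchSize)
    acc <- c(total = 0, recon = 0, dict = 0, commit = 0, mis = 0, div = 0)
    nb <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, nrow(Xtr))]
      lg <- .svqLossGrad(params, Xtr[idx, , drop = FALSE], ytr[idx], cfg)
      if (!is.finite(lg$total))
        stop("training diverged (non-finite loss) at epoch ", ep)
      up <- .adamStep(params, lg$grads, st, cfg$learningRate)
      params <- up$params; st <- up$state
      acc <- acc + c(lg$total, lg$reconstruction, lg$dictionary,
                     lg$commitment, lg$misclassDictionary, lg$divergence)
      nb <- nb + 1L
    }
    acc <- acc / nb
    valAcc <- if (nrow(Xval)) {
      zev <- .svqEncode(params, Xval, cfg)$ze
      mean(nearestEmbedding(params[["E"]], zev) == yval)
    } else NA_real_
    log[[ep]] <- data.frame(epoch = ep, total = acc[1], recon = acc[2],
                            dictionary = acc[3], commitment = acc[4],
                            misclass = acc[5], divergence = acc[6],
                            val_match = valAcc)
    if (verbose && ep %% 20L == 0L)
      message(sprintf("epoch %d: loss %.4f val match %.3f",
                      ep, acc[1], valAcc))
  }
  E <- params[["E"]]
  rownames(E) <- classLabels
  params[["E"]] <- NULL
  # per-class diagonal variance of final training encodings, for generation
  zeAll <- .svqEncode(params, Xtr, cfg)$ze
  latentVar <- t(vapply(seq_along(classLabels), function(ci) {
    zz <- zeAll[ytr == ci, , drop = FALSE]
    if (nrow(zz) < 2L) rep(0, ncol(zz)) else apply(zz, 2, stats::var)
  }, numeric(cfg$embeddingDim)))
  rownames(latentVar) <- classLabels
  gid <- if (is(data, "PerturbationExperiment")) geneIds(data)
         else colnames(X)
  if (is.null(gid)) gid <- paste0("gene", seq_len(ncol(X)))
  new("SVQVAEModel", params = params, codebook = E,
      classLabels = classLabels,
      classCounts = as.integer(table(factor(labels[sp$train],
                                            levels = classLabels))),
      latentVar = latentVar, config = unclass(cfg),
      trainingLog = do.call(rbind, log), geneIds = gid)
}

#' Class-conditional (or unconditional) generation from an S-VQ-VAE
#'
#' Ancestral sampling: draw a code `z ~ N(e_y, diag(sigma2))` where
#' `sigma2` is the per-class diagonal variance of the training encodings,
#' then decode. When `y` is NULL the class is first drawn from the
#' training-set multinomial over classes.
#'
#' @param model A [SVQVAEModel-class].
#' @param y class label (or index), or NULL for unconditional sampling.
#' @param n number of samples (> 0).
#' @param sigma2 optional variance vector overriding the stored estimate.
#' @param seed integer seed.
#' @return A [PerturbationExperiment-class] with the sampled class in
#'   `pcl_label`.
#' @export
generateClassConditional <- function(model, y = NULL, n, sigma2 = NULL,
                                     seed = 1L) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  if (is.null(y)) {
    if (sum(model@classCounts) == 0L) stop("no training class counts stored")
    yIdx <- sample.int(length(model@classLabels), n, replace = TRUE,
                       prob = model@classCounts / sum(model@classCounts))
  } else {
    yIdx <- rep(.labelIdx(model, y), length.out = n)
    if (model@classCounts[yIdx[1]] == 0L)
      stop("class was never seen in training: ", model@classLabels[yIdx[1]])
  }
  D <- ncol(model@codebook)
  s2 <- if (is.null(sigma2)) model@latentVar[yIdx, , drop = FALSE]
        else matrix(sigma2, n, D, byrow = TRUE)
  Z <- model@codebook[yIdx, , drop = FALSE] +
    sqrt(s2) * matrix(stats::rnorm(n * D), nrow = n)
  Xhat <- decodeCode(model, Z)
  rownames(Xhat) <- sprintf("svqgen%05d", seq_len(n))
  meta <- data.frame(perturbagen_id = "generated", pert_type = "control",
                     cell_line = "generated",
                     pcl_label = model@classLabels[yIdx],
                     row.names = rownames(Xhat), stringsAsFactors = FALSE)
  PerturbationExperiment(Xhat, meta, geneIds = model@geneIds,
                         zrange = c(-model@config$outputScale,
                                    model@config$outputScale))
}

#' Codebook (embedding space) of a trained S-VQ-VAE
#'
#' @param model A [SVQVAEModel-class].
#' @return numeric matrix, one row per class, row names = class labels.
#' @export
codebook <- function(model) model@codebook

#' Class labels of a trained S-VQ-VAE
#' @param model A [SVQVAEModel-class].
#' @export
classLabels <- function(model) model@classLabels

setMethod("show", "SVQVAEModel", function(object) {
  cat("SVQVAEModel:", object@config$inputDim, "->",
      paste(object@config$hiddenSizes, collapse = "-"), "-> D =",
      object@config$embeddingDim, "\n")
  cat("  codebook:", nrow(object@codebook), "classes\n")
  if (nrow(object@trainingLog)) {
    lastRow <- object@trainingLog[nrow(object@trainingLog), ]
    cat(sprintf("  trained %d epochs; final val nearest-code match %.3f\n",
                nrow(object@trainingLog), lastRow$val_match))
  }
  invisible(NULL)
})
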