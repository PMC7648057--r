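#' Extract a per-sample representation from a trained VAE
#'
#' The seven representation types are the raw profile (`"raw"`), the
#' encoder hidden layers (`"enc1"`, `"enc2"`, ...), the deterministic
#' posterior mean at the top hidden layer (`"top"`), the signature-node
#' subset of the top layer (`"signature"`, requires signature nodes to have
#' been attached to the model), and the decoder hidden layers (`"dec1"`,
#' ...) obtained by continuing the deterministic forward pass from the
#' posterior mean (post-activation values).
#'
#' @param model A [VAEModel-class].
#' @param data [PerturbationExperiment-class] or samples x genes matrix.
#' @param layerTag one of the tags above.
#' @return numeric matrix (samples x width) with a `layer_tag` attribute.
#' @export
extractRepresentation <- function(model, data, layerTag = "top") {
  X <- .asSampleMatrix(data)
  cfg <- model@config
  nh <- length(.vaeDims(cfg)$hidden)
  valid <- c("raw", paste0("enc", seq_len(nh)), "top", "signature",
             paste0("dec", seq_len(nh)))
  if (!layerTag %in% valid)
    stop("layerTag must be one of: ", paste(valid, collapse = ", "))
  out <- if (layerTag == "raw") {
    X
  } else if (grepl("^enc", layerTag)) {
    i <- as.integer(sub("enc", "", layerTag))
    .tanhStack(X, model@params, "enc", i)[[i + 1L]]
  } else {
    enc <- .vaeEncodeForward(model@params, X, cfg)
    if (layerTag == "top") enc$mu
    else if (layerTag == "signature") {
      if (!length(model@signature))
        stop("no signature nodes attached; run findSignatureNodes() and ",
             "assign with signatureNodes(model) <- result$indices")
      enc$mu[, model@signature, drop = FALSE]
    } else {
      i <- as.integer(sub("dec", "", layerTag))
      .tanhStack(enc$mu, model@params, "dec", i)[[i + 1L]]
    }
  }
  rownames(out) <- rownames(X)
  attr(out, "layer_tag") <- layerTag
  out
}

#' Signature nodes of a model
#'
#' Signature nodes are the small subset of top-hidden-layer units with large
#' mean absolute activation that carry the primary characteristics of a
#' profile; they are discovered with [findSignatureNodes()] and attached to
#' the model so that the `"signature"` representation becomes available.
#'
#' @param model A [VAEModel-class].
#' @param value integer vector of node indices.
#' @return `signatureNodes` returns the indices (possibly empty).
#' @export
signatureNodes <- function(model) model@signature

#' @rdname signatureNodes
#' @export
`signatureNodes<-` <- function(model, value) {
  value <- sort(unique(as.integer(value)))
  latent <- .vaeDims(model@config)$latent
  if (length(value) && (min(value) < 1L || max(value) > latent))
    stop("signature indices must lie in [1, ", latent, "]")
  model@signature <- value
  model
}

#' Discover signature nodes by 2-means on mean absolute activation
#'
#' Computes each top-layer node's mean absolute activation over a reference
#' dataset and splits nodes into a low and a high group by exact 1-d
#' 2-means (search over sorted split points, so the global optimum is found
#' deterministically). The high group is returned, with per-node variance
#' attached. When the two group means differ by less than a factor of 2 the
#' bimodality is considered degenerate and a warning is emitted (the high
#' group is still returned).
#'
#' @param codes top-layer representation matrix (samples x nodes), e.g.
#'   `extractRepresentation(model, data, "top")`.
#' @return list of class `"SignatureNodeSet"`: `indices`, `meanAbs` (all
#'   nodes), `variance` (all nodes), `groupMeans` (low, high).
#' @export
findSignatureNodes <- function(codes) {
  if (nrow(codes) < 2L) stop("need at least 2 samples")
  stat <- colMeans(abs(codes))
  v <- apply(codes, 2, stats::var)
  m <- length(stat)
  ord <- order(stat)
  s <- stat[ord]
  # exact 2-means on the sorted 1-d statistic: evaluate every split
  cum <- cumsum(s); tot <- cum[m]
  best <- NULL; bestWss <- Inf
  for (p in seq_len(m - 1L)) {
    m1 <- cum[p] / p
    m2 <- (tot - cum[p]) / (m - p)
    wss <- sum((s[1:p] - m1)^2) + sum((s[(p + 1):m] - m2)^2)
    if (wss < bestWss - 1e-12 ||
        (abs(wss - bestWss) <= 1e-12 && !is.null(best) && p > best)) {
      bestWss <- wss; best <- p
    }
  }
  low <- ord[seq_len(best)]
  high <- ord[(best + 1L):m]
  gm <- c(low = mean(stat[low]), high = mean(stat[high]))
  if (gm["high"] < 2 * gm["low"])
    warning("weak bimodality: high/low group means ratio < 2 (",
            sprintf("%.3f vs %.3f", gm["high"], gm["low"]), ")")
  structure(list(indices = sort(high), meanAbs = stat, variance = v,
                 groupMeans = gm),
            class = "SignatureNodeSet")
}

#' Per-class signature-node patterns
#'
#' Averages the signature-node activations over each major perturbagen
#' class, giving one signed pattern vector per class.
#'
#' @param codes top-layer representation matrix (samples x nodes).
#' @param labels per-sample class labels (NA allowed; those samples are
#'   ignored).
#' @param signature a `SignatureNodeSet` or integer vector of node indices.
#' @param majorMin minimum treated-sample count for a class to be included
#'   (default 150).
#' @return matrix: one row per major class (row names = labels), one column
#'   per signature node; attribute `n` holds per-class sample counts.
#' @export
pclSignaturePattern <- function(codes, labels, signature, majorMin = 150L) {
  idx <- if (inherits(signature, "SignatureNodeSet")) signature$indices
         else as.integer(signature)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  tab <- table(labels[keep])
  major <- names(tab)[tab >= majorMin]
  if (!length(major)) stop("no class reaches the majorMin threshold")
  pat <- t(vapply(major, function(cl)
    colMeans(codes[keep & labels == cl, idx, drop = FALSE]),
    numeric(length(idx))))
  colnames(pat) <- paste0("node", idx)
  attr(pat, "n") <- as.integer(tab[major])
  attr(pat, "signature") <- idx
  pat
}

#' Generate profiles from a class signature pattern
#'
#' Builds latent vectors whose signature positions are fixed to the pattern
#' values while every other position is drawn from a standard normal, then
#' decodes them — simulating new samples of the class the pattern was
#' averaged from.
#'
#' @param model A [VAEModel-class].
#' @param pattern numeric vector of per-signature-node values (one row of
#'   [pclSignaturePattern()]).
#' @param signature `SignatureNodeSet` or integer indices; defaults to the
#'   signature attached to the model.
#' @param n number of samples to generate (default 500).
#' @param seed integer seed.
#' @return A [PerturbationExperiment-class] of generated profiles.
#' @export
generateFromPattern <- function(model, pattern, signature = NULL, n = 500L,
                                seed = 1L) {
  idx <- if (is.null(signature)) model@signature
         else if (inherits(signature, "SignatureNodeSet")) signature$indices
         else as.integer(signature)
  if (!length(idx)) stop("no signature nodes given or attached to the model")
  if (length(pattern) != length(idx))
    stop("pattern length must match the number of signature nodes")
  set.seed(seed)
  latent <- .vaeDims(model@config)$latent
  Z <- matrix(stats::rnorm(n * latent), nrow = n)
  Z[, idx] <- matrix(pattern, n, length(idx), byrow = TRUE)
  Xhat <- decodeLatent(model, Z)
  rownames(Xhat) <- sprintf("pat%05d", seq_len(n))
  meta <- data.frame(perturbagen_id = rep("pattern_generated", n),
                     pert_type = "control", cell_line = "generated",
                     row.names = rownames(Xhat), stringsAsFactors = FALSE)
  PerturbationExperiment(Xhat, meta, geneIds = model@geneIds,
                         zrange = c(-model@config$outputScale,
                                    model@config$outputScale))
}

#' Euclidean nearest real neighbour of each generated profile
#'
#' Exhaustive nearest-neighbour search in gene space. The label composition
#' of the matched neighbours (fraction of generated samples whose nearest
#' real sample carries each class label) is attached as the `composition`
#' attribute.
#'
#' @param generated [PerturbationExperiment-class] or matrix of generated
#'   profiles.
#' @param real [PerturbationExperiment-class] with `pcl_label` metadata, or
#'   a matrix (then `realLabels` must be given).
#' @param realLabels optional label vector for matrix input.
#' @return data.frame with `neighbor_id`, `neighbor_label`, `distance`, one
#'   row per generated sample; attribute `composition` is a named fraction
#'   vector summing to 1.
#' @export
nearestRealNeighbor <- function(generated, real, realLabels = NULL) {
  G <- .asSampleMatrix(generated)
  R <- .asSampleMatrix(real)
  if (ncol(G) != ncol(R))
    stop("generated and real data are in different gene spaces")
  if (is.null(realLabels)) {
    if (!is(real, "PerturbationExperiment"))
      stop("realLabels required for matrix input")
    realLabels <- sampleInfo(real)$pcl_label
  }
  # ||g - r||^2 = ||g||^2 - 2 g.r + ||r||^2, minimized per generated row
  cross <- G %*% t(R)
  d2 <- sweep(-2 * cross, 2, rowSums(R^2), "+")
  nn <- apply(d2, 1L, which.min)
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(G)), nn)] + rowSums(G^2), 0))
  qid <- rownames(G)
  if (is.null(qid)) qid <- as.character(seq_len(nrow(G)))
  out <- data.frame(query_id = qid, neighbor_id = rownames(R)[nn],
                    neighbor_label = as.character(realLabels)[nn],
                    distance = dist, stringsAsFactors = FALSE)
  comp <- table(out$neighbor_label, useNA = "ifany") / nrow(out)
  attr(out, "composition") <- comp
  out
}
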