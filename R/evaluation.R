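#' Mixing score of a binary-categorical clustering
#'
#' For two categories distributed over k clusters with per-cluster counts
#' `(p_i, q_i)`, the mixing score is `sum_i max(p_i, q_i) / N` — the average
#' proportion of the dominant category per cluster. 0.5 means the two
#' categories mix evenly in every cluster; 1 means complete separation.
#'
#' @param labels category per item (exactly two distinct values).
#' @param clusters cluster id per item (same length).
#' @return list of class `"MixingScoreResult"`: `score`, `k`, `N`,
#'   `perCluster` (data.frame cluster/p/q).
#' @export
mixingScore <- function(labels, clusters) {
  if (length(labels) != length(clusters))
    stop("labels and clusters must have the same length")
  cats <- unique(labels)
  if (length(cats) != 2L)
    stop("mixing score is defined for exactly two categories, got ",
         length(cats))
  tab <- table(factor(clusters), factor(labels, levels = cats))
  per <- data.frame(cluster = rownames(tab), p = as.integer(tab[, 1]),
                    q = as.integer(tab[, 2]), stringsAsFactors = FALSE)
  score <- sum(pmax(per$p, per$q)) / length(labels)
  structure(list(score = score, k = nrow(per), N = length(labels),
                 perCluster = per),
            class = "MixingScoreResult")
}

#' Real-vs-generated mixing protocol
#'
#' Repeats the indistinguishability protocol: generate `nEach` profiles from
#' the trained VAE, sample `nEach` real profiles, hierarchically cluster the
#' union with distance 1 - Pearson correlation (average linkage), cut the
#' dendrogram at `k` clusters, and compute the mixing score of the
#' real/generated labelling. Reports the per-repeat scores, their mean and a
#' 2.5/97.5 percentile confidence interval.
#'
#' @param model A [VAEModel-class].
#' @param data [PerturbationExperiment-class] or samples x genes matrix of
#'   real profiles (at least `nEach` rows).
#' @param nEach samples of each category per repeat (default 2000).
#' @param k dendrogram cut height in clusters (default 10).
#' @param repeats number of repeats (default 50).
#' @param seed integer root seed.
#' @return list: `scores`, `mean`, `ci` (2.5% and 97.5% percentiles), `k`,
#'   `nEach`, `linkage`.
#' @export
realVsGeneratedMixing <- function(model, data, nEach = 2000L, k = 10L,
                                  repeats = 50L, seed = 1L) {
  X <- .asSampleMatrix(data)
  if (nrow(X) < nEach)
    stop("data has fewer than nEach = ", nEach, " samples")
  scores <- numeric(repeats)
  for (r in seq_len(repeats)) {
    gen <- sampleMatrix(generateSamples(model, nEach, seed = seed + r))
    set.seed(seed + 100000L + r)
    real <- X[sample.int(nrow(X), nEach), , drop = FALSE]
    M <- rbind(gen, real)
    if (any(apply(M, 1, stats::sd) == 0))
      stop("constant profile encountered: Pearson distance undefined")
    d <- stats::as.dist(1 - stats::cor(t(M)))
    cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
    lab <- rep(c("generated", "real"), each = nEach)
    scores[r] <- mixingScore(lab, cl)$score
  }
  list(scores = scores, mean = mean(scores),
       ci = stats::quantile(scores, c(0.025, 0.975), names = FALSE),
       k = k, nEach = nEach, linkage = "average")
}

#' Nearest-neighbour perturbagen-class graph with Louvain communities
#'
#' Each class row of the input matrix (codebook or per-class pattern matrix)
#' is compared with every other by Pearson correlation; for each class a
#' directed edge is added from its maximally correlated partner (source) to
#' the class itself (target), weighted by the correlation. Louvain
#' communities (resolution 1, edge weights used) and the corresponding
#' modularity are computed on the undirected collapse of the graph.
#'
#' @param E numeric matrix with one row per class (row names = labels).
#' @param louvainRestarts number of seeded Louvain restarts; the partition
#'   with the best modularity is kept (default 1, deterministic under
#'   `seed`).
#' @param seed integer seed for Louvain.
#' @return list of class `"PCLGraph"`: `graph` (directed igraph), `edges`
#'   (data.frame source/target/weight/community of target), `membership`
#'   (named vector), `modularity`, `correlations` (full matrix).
#' @export
pclGraph <- function(E, louvainRestarts = 1L, seed = 1L) {
  if (nrow(E) < 3L) stop("need at least 3 classes")
  if (is.null(rownames(E))) rownames(E) <- paste0("class", seq_len(nrow(E)))
  sds <- apply(E, 1, stats::sd)
  if (any(sds == 0))
    stop("constant representation row(s): ",
         paste(rownames(E)[sds == 0], collapse = ", "),
         " (Pearson correlation undefined)")
  C <- stats::cor(t(E))
  diag(C) <- -Inf
  nn <- apply(C, 1L, which.max)
  edges <- data.frame(source = rownames(E)[nn], target = rownames(E),
                      weight = C[cbind(seq_len(nrow(E)), nn)],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = rownames(E))
  # Louvain needs an undirected graph; collapse parallel edges, keep the
  # stronger weight. Shift weights to be positive (correlations can be < 0).
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(weight = "max"))
  w <- igraph::E(gu)$weight
  wpos <- w - min(0, min(w)) + 1e-9
  best <- NULL
  for (r in seq_len(louvainRestarts)) {
    set.seed(seed + r - 1L)
    cm <- igraph::cluster_louvain(gu, weights = wpos, resolution = 1)
    if (is.null(best) ||
        igraph::modularity(cm) > igraph::modularity(best)) best <- cm
  }
  memb <- igraph::membership(best)
  names(memb) <- igraph::V(gu)$name
  edges$community <- as.integer(memb[edges$target])
  structure(list(graph = g, edges = edges,
                 membership = memb,
                 modularity = igraph::modularity(best),
                 correlations = {diag(C) <- 1; C}),
            class = "PCLGraph")
}

#' Export a PCL graph
#'
#' @param pg A `"PCLGraph"` from [pclGraph()].
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"` (delimited
#'   source/target/weight/community).
#' @export
exportGraph <- function(pg, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- pg$graph
    igraph::V(g)$community <- as.integer(pg$membership[igraph::V(g)$name])
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(pg$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.cohenKappa <- function(truth, pred) {
  lev <- union(truth, pred)
  tab <- table(factor(truth, lev), factor(pred, lev))
  N <- sum(tab)
  po <- sum(diag(tab)) / N
  pe <- sum(rowSums(tab) * colSums(tab)) / N^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Cross-validated class prediction from sample representations
#'
#' Ten-fold cross-validation of two linear multi-class classifier families —
#' multinomial logistic regression (`nnet::multinom`) and a linear-kernel
#' support vector machine (`e1071::svm`) — on one or more representation
#' matrices. Reports mean fold accuracy and Cohen's kappa (from pooled
#' out-of-fold predictions) per representation type, plus the random-guess
#' baseline `sum_c (n_c / N)^2` for the observed (possibly uneven) class
#' distribution.
#'
#' @param reps a representation matrix or a named list of matrices (rows =
#'   samples, aligned with `labels`).
#' @param labels class label per sample.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold split.
#' @param models which classifier families to run.
#' @return data.frame: `representation`, `model`, `accuracy`, `kappa`;
#'   attribute `baseline` holds the random-guess accuracy.
#' @export
pclClassification <- function(reps, labels, folds = 10L, seed = 1L,
                              models = c("LR", "SVM")) {
  if (is.matrix(reps)) reps <- list(representation = reps)
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need at least two classes")
  small <- names(which(table(labels) < folds))
  if (length(small))
    warning("class(es) with fewer samples than folds: ",
            paste(small, collapse = ", "))
  n <- length(labels)
  set.seed(seed)
  fold <- integer(n)
  for (cl in levels(labels)) {       # stratified fold assignment
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  out <- list()
  for (nm in names(reps)) {
    M <- reps[[nm]]
    stopifnot(nrow(M) == n)
    for (family in models) {
      pred <- factor(rep(NA_character_, n), levels = levels(labels))
      accs <- numeric(folds)
      for (f in seq_len(folds)) {
        tr <- fold != f; te <- !tr
        if (!any(te)) next
        df <- data.frame(y = labels[tr], M[tr, , drop = FALSE])
        ndf <- data.frame(M[te, , drop = FALSE])
        colnames(ndf) <- colnames(df)[-1]
        p <- if (family == "LR") {
          fit <- nnet::multinom(y ~ ., data = df, trace = FALSE,
                                MaxNWts = 100000, maxit = 200)
          stats::predict(fit, newdata = ndf)
        } else {
          fit <- e1071::svm(y ~ ., data = df, kernel = "linear")
          stats::predict(fit, newdata = ndf)
        }
        pred[te] <- p
        accs[f] <- mean(p == labels[te])
      }
      out[[length(out) + 1L]] <- data.frame(
        representation = nm, model = family,
        accuracy = mean(accs),
        kappa = .cohenKappa(as.character(labels), as.character(pred)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "baseline") <- sum((table(labels) / n)^2)
  res
}

#' Correlation-ranked drug-target retrieval
#'
#' For every sample treated with a drug, computes the Pearson correlation of
#' its representation with the representation of every knockdown sample;
#' each knocked-down gene is scored by its best-correlated sample, genes are
#' ranked by decreasing score (ties broken by gene symbol), and the rank of
#' the best-ranked known target is recorded. Per drug, `top_rank` is the
#' minimum and `mean_rank` the mean of this per-sample rank. Rank 1 is best.
#'
#' Drugs absent from the truth table (or whose targets are absent from the
#' knockdown set) are skipped with a message.
#'
#' @param drugReps representation matrix of drug-treated samples.
#' @param drugIds drug id per drug sample.
#' @param gpReps representation matrix of knockdown samples (same layer and
#'   dimension as `drugReps`).
#' @param gpGenes knocked-down gene symbol per knockdown sample.
#' @param truth data.frame with `drug_id`, `target_gene` (see
#'   [readDrugTargets()]).
#' @return list of class `"RetrievalResult"`: `summary` (data.frame
#'   drug_id/n_samples/top_rank/mean_rank), `ranks` (data.frame drug_id/
#'   sample_id/target_gene/rank for every known target), `nGenes`.
#' @export
rankTargets <- function(drugReps, drugIds, gpReps, gpGenes, truth) {
  if (ncol(drugReps) != ncol(gpReps))
    stop("drug and knockdown representations have different dimensions")
  drugIds <- as.character(drugIds)
  gpGenes <- as.character(gpGenes)
  genes <- sort(unique(gpGenes))
  C <- stats::cor(t(drugReps), t(gpReps))  # drug samples x gp samples
  summary <- list(); rankRows <- list()
  for (drug in unique(drugIds)) {
    targets <- truth$target_gene[truth$drug_id == drug]
    if (!length(targets)) {
      message("drug not in truth table, skipped: ", drug)
      next
    }
    targets <- intersect(targets, genes)
    if (!length(targets)) {
      message("no target of ", drug, " present in the knockdown set, skipped")
      next
    }
    rows <- which(drugIds == drug)
    topPerSample <- numeric(length(rows))
    for (i in seq_along(rows)) {
      cc <- C[rows[i], ]
      geneScore <- vapply(split(cc, gpGenes), max, numeric(1))[genes]
      ord <- order(-geneScore, genes)          # ties by gene symbol
      rk <- match(genes, genes[ord])
      names(rk) <- genes
      topPerSample[i] <- min(rk[targets])
      rankRows[[length(rankRows) + 1L]] <- data.frame(
        drug_id = drug,
        sample_id = if (is.null(rownames(drugReps))) as.character(rows[i])
                    else rownames(drugReps)[rows[i]],
        target_gene = targets, rank = unname(rk[targets]),
        stringsAsFactors = FALSE)
    }
    summary[[length(summary) + 1L]] <- data.frame(
      drug_id = drug, n_samples = length(rows),
      top_rank = min(topPerSample), mean_rank = mean(topPerSample),
      stringsAsFactors = FALSE)
  }
  if (!length(summary)) stop("no drug could be evaluated against the truth")
  structure(list(summary = do.call(rbind, summary),
                 ranks = do.call(rbind, rankRows),
                 nGenes = length(genes)),
            class = "RetrievalResult")
}

#' Recall and hit-proportion aggregates of a retrieval result
#'
#' `recall@n` is the mean over samples of the fraction of a drug's known
#' targets retrieved in the top n ranked genes; `hit@n` is the fraction of
#' samples with at least one known target in the top n.
#'
#' @param res A `"RetrievalResult"` from [rankTargets()].
#' @param nValues integer vector of cutoffs (values above the gene count are
#'   clipped with a warning).
#' @return data.frame: `n`, `recall`, `hit`.
#' @export
retrievalAggregates <- function(res, nValues = c(1L, 3L, 5L, 10L)) {
  stopifnot(inherits(res, "RetrievalResult"))
  if (any(nValues > res$nGenes)) {
    warning("cutoff(s) above the gene count clipped to ", res$nGenes)
    nValues <- pmin(nValues, res$nGenes)
  }
  rk <- res$ranks
  key <- paste(rk$drug_id, rk$sample_id)
  out <- lapply(unique(nValues), function(n) {
    bySample <- vapply(split(rk$rank, key),
                       function(r) c(mean(r <= n), any(r <= n)), numeric(2))
    data.frame(n = n, recall = mean(bySample[1, ]),
               hit = mean(bySample[2, ]))
  })
  do.call(rbind, out)
}
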