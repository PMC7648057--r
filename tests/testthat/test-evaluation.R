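test_that("mixing score matches hand evaluation and brute force", {
  # clusters {3A, 1B} and {1A, 3B}: (3 + 3) / 8
  lab <- c(rep("A", 3), "B", "A", rep("B", 3))
  cl <- c(rep(1, 4), rep(2, 4))
  expect_equal(mixingScore(lab, cl)$score, 0.75)
  # perfectly separated clusters score 1
  expect_equal(mixingScore(c("A", "A", "B", "B"), c(1, 1, 2, 2))$score, 1)
  # even mixture in every cluster scores 0.5
  expect_equal(mixingScore(c("A", "B", "A", "B"), c(1, 1, 2, 2))$score, 0.5)
  expect_error(mixingScore(c("A", "B", "C"), c(1, 1, 2)), "two categories")
  res <- mixingScore(lab, cl)
  expect_identical(sum(res$perCluster$p + res$perCluster$q), res$N)
  # oracle equivalence on random instances
  set.seed(99)
  for (i in 1:50) {
    N <- sample(4:200, 1)
    labels <- sample(c("real", "generated"), N, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("real", "generated")
    clusters <- sample.int(sample(2:10, 1), N, replace = TRUE)
    ms <- mixingScore(labels, clusters)$score
    expect_identical(ms, bruteMixing(labels, clusters))
    expect_gte(ms, 0.5); expect_lte(ms, 1)
  }
})

test_that("hierarchical mixing protocol behaves at the extremes", {
  # an exact copy of the data mixes perfectly: every cluster is duplicated
  set.seed(12)
  M <- matrix(rnorm(40 * 10), 40)
  dup <- rbind(M, M + rnorm(length(M), sd = 1e-9))
  lab <- rep(c("generated", "real"), each = 40)
  d <- as.dist(1 - cor(t(dup)))
  cl <- cutree(hclust(d, method = "average"), k = 5)
  expect_equal(mixingScore(lab, cl)$score, 0.5)
  # two clouds with disjoint correlation structure separate completely:
  # each cloud shares its own strong gene pattern (Pearson distance is
  # blind to mean shifts, so a location offset alone would not separate)
  pattA <- rnorm(10); pattB <- rnorm(10)
  M2 <- rbind(outer(rnorm(40, mean = 3, sd = 0.2), pattA) +
                matrix(rnorm(40 * 10, sd = 0.02), 40),
              outer(rnorm(40, mean = 3, sd = 0.2), pattB) +
                matrix(rnorm(40 * 10, sd = 0.02), 40))
  cl2 <- cutree(hclust(as.dist(1 - cor(t(M2))), method = "average"),
                k = 10)
  expect_equal(mixingScore(lab, cl2)$score, 1)
  # the distance is invariant to per-sample affine rescaling
  M3 <- M * 3 + 7
  expect_equal(as.matrix(as.dist(1 - cor(t(M3)))),
               as.matrix(as.dist(1 - cor(t(M)))), tolerance = 1e-12)
})

test_that("real-vs-generated protocol returns seeded score distributions", {
  m <- fixtureVAE()
  res <- realVsGeneratedMixing(m, fixtureSim()$data, nEach = 200L, k = 10L,
                               repeats = 3L, seed = 6L)
  expect_length(res$scores, 3L)
  expect_true(all(res$scores >= 0.5 & res$scores <= 1))
  expect_equal(res$mean, mean(res$scores))
  res2 <- realVsGeneratedMixing(m, fixtureSim()$data, nEach = 200L,
                                k = 10L, repeats = 3L, seed = 6L)
  expect_identical(res$scores, res2$scores)
  expect_error(realVsGeneratedMixing(m, fixtureSim()$data, nEach = 1e6L),
               "fewer")
})

test_that("nearest-neighbour class graph matches a brute-force oracle", {
  set.seed(31)
  E <- matrix(rnorm(5 * 8), 5, dimnames = list(paste0("C", 1:5), NULL))
  pg <- pclGraph(E)
  C <- cor(t(E))
  for (i in 1:5) {
    expected <- setdiff(names(sort(C[i, ], decreasing = TRUE)),
                        rownames(E)[i])[1]
    got <- pg$edges$source[pg$edges$target == rownames(E)[i]]
    expect_identical(got, expected)
  }
  # every node has exactly one incoming nearest-partner edge, no self loops
  expect_identical(sort(pg$edges$target), sort(rownames(E)))
  expect_false(any(pg$edges$source == pg$edges$target))
  # duplicated rows are mutually nearest: a bidirectional pair
  E2 <- rbind(E, C6 = E["C1", ])
  pg2 <- pclGraph(E2)
  expect_identical(pg2$edges$source[pg2$edges$target == "C1"], "C6")
  expect_identical(pg2$edges$source[pg2$edges$target == "C6"], "C1")
  expect_error(pclGraph(rbind(E, K = rep(1, 8))), "constant")
  expect_error(pclGraph(E[1:2, ]), "at least 3")
})

test_that("modularity agrees with the standard formula", {
  set.seed(8)
  E <- matrix(rnorm(6 * 10), 6, dimnames = list(paste0("C", 1:6), NULL))
  pg <- pclGraph(E)
  gu <- igraph::as_undirected(pg$graph, mode = "collapse",
                              edge.attr.comb = list(weight = "max"))
  w <- igraph::E(gu)$weight
  w <- w - min(0, min(w)) + 1e-9
  A <- igraph::as_adjacency_matrix(gu, attr = NULL, sparse = FALSE)
  # hand-computed weighted modularity Q = sum_ij (w_ij - k_i k_j / 2m)
  #                                        * delta(c_i, c_j) / 2m
  W <- A * 0
  el <- igraph::as_edgelist(gu)
  for (r in seq_len(nrow(el))) {
    W[el[r, 1], el[r, 2]] <- w[r]; W[el[r, 2], el[r, 1]] <- w[r]
  }
  k <- rowSums(W); m2 <- sum(W)
  memb <- pg$membership[rownames(W)]
  Q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W)))
    if (memb[i] == memb[j]) Q <- Q + W[i, j] - k[i] * k[j] / m2
  expect_equal(pg$modularity, unname(Q / m2), tolerance = 1e-10)
})

test_that("classification harness separates what is separable", {
  sim <- fixtureSimSmall()
  lab <- sampleInfo(sim$data)$pcl_label
  X <- sampleMatrix(sim$data)
  res <- pclClassification(list(raw = X), lab, folds = 5L, seed = 3L)
  expect_true(all(res$accuracy > 0.9))
  expect_true(all(res$kappa > 0.9))
  expect_equal(attr(res, "baseline"), sum((table(lab) / length(lab))^2))
  # label-shuffled control collapses to the baseline
  set.seed(4)
  resShuf <- pclClassification(list(raw = X), sample(lab), folds = 5L,
                               seed = 3L)
  expect_lt(max(resShuf$accuracy), attr(resShuf, "baseline") + 3 *
              sqrt(attr(resShuf, "baseline") / length(lab)) + 0.1)
  expect_lt(max(abs(resShuf$kappa)), 0.15)
  # constant predictions give kappa 0
  expect_equal(perturbDGM:::.cohenKappa(c("a", "b", "a", "b"),
                                        c("a", "a", "a", "a")), 0)
  expect_error(pclClassification(X, rep("A", nrow(X))), "two classes")
})

test_that("retrieval ranks planted targets first", {
  # a drug profile identical to its target knockdown ranks it 1
  set.seed(21)
  gp <- matrix(rnorm(6 * 10), 6)
  gpGenes <- c("G1", "G1", "G2", "G3", "G4", "G5")
  drug <- gp[3, , drop = FALSE] + rnorm(10, sd = 1e-6)
  truth <- data.frame(drug_id = "dX", target_gene = "G2")
  res <- rankTargets(drug, "dX", gp, gpGenes, truth)
  expect_equal(res$summary$top_rank, 1)
  expect_equal(res$summary$mean_rank, 1)
  # an anti-correlated decoy ranks last
  gp2 <- rbind(gp, -drug[1, ] * 2)
  res2 <- rankTargets(drug, "dX", gp2, c(gpGenes, "DECOY"),
                      rbind(truth, data.frame(drug_id = "dX",
                                              target_gene = "DECOY")))
  decoyRank <- res2$ranks$rank[res2$ranks$target_gene == "DECOY"]
  expect_equal(decoyRank, 6)               # 6 distinct genes
  # invariance to gene order and to positive affine transforms
  perm <- sample(nrow(gp))
  resP <- rankTargets(drug, "dX", gp[perm, ], gpGenes[perm], truth)
  expect_equal(resP$summary$top_rank, res$summary$top_rank)
  resA <- rankTargets(drug * 2 + 5, "dX", gp * 2 + 5, gpGenes, truth)
  expect_equal(resA$summary$top_rank, res$summary$top_rank)
  # drugs missing from the truth table are skipped with a notice
  expect_message(
    rankTargets(rbind(drug, drug), c("dX", "dY"), gp, gpGenes, truth),
    "skipped")
})

test_that("recall and hit aggregates match hand counts", {
  # two targets at ranks 1 and 5: recall@3 = 0.5, hit@3 = 1
  res <- structure(list(
    summary = data.frame(drug_id = "d", n_samples = 1, top_rank = 1,
                         mean_rank = 1),
    ranks = data.frame(drug_id = "d", sample_id = "s1",
                       target_gene = c("G1", "G2"), rank = c(1, 5)),
    nGenes = 10L), class = "RetrievalResult")
  agg <- retrievalAggregates(res, nValues = c(1L, 3L, 10L))
  expect_equal(agg$recall[agg$n == 1], 0.5)
  expect_equal(agg$recall[agg$n == 3], 0.5)
  expect_equal(agg$hit[agg$n == 3], 1)
  expect_equal(agg$recall[agg$n == 10], 1)     # n = all genes
  expect_warning(retrievalAggregates(res, nValues = 50L), "clipped")
})

test_that("planted-twin benchmark retrieval beats a shuffled control", {
  bm <- simulateDrugTargetBenchmark(
    syntheticConfig(seed = 44L, samplesPerClass = 10L), nDistractors = 20L)
  res <- rankTargets(sampleMatrix(bm$smp),
                     sampleInfo(bm$smp)$perturbagen_id,
                     sampleMatrix(bm$gp), sampleInfo(bm$gp)$target_gene,
                     bm$truth)
  expect_lte(median(res$summary$top_rank), 3)
  set.seed(7)
  sh <- bm$truth
  sh$target_gene <- sample(setdiff(unique(sampleInfo(bm$gp)$target_gene),
                                   bm$truth$target_gene), nrow(sh))
  resS <- rankTargets(sampleMatrix(bm$smp),
                      sampleInfo(bm$smp)$perturbagen_id,
                      sampleMatrix(bm$gp), sampleInfo(bm$gp)$target_gene,
                      sh)
  expect_lt(median(res$summary$top_rank), median(resS$summary$top_rank))
})
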