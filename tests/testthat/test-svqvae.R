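test_that("nearest-code lookup is exact with lowest-index ties", {
  E <- rbind(c(0, 0), c(10, 10), c(3, 4))
  expect_identical(nearestEmbedding(E, c(1, 1)), 1L)
  expect_identical(nearestEmbedding(E, E[3, ]), 3L)
  # equidistant codes: lower index wins
  Et <- rbind(c(1, 0), c(-1, 0))
  expect_identical(nearestEmbedding(Et, c(0, 5)), 1L)
  expect_identical(nearestEmbedding(E, rbind(c(1, 1), c(9, 9))), c(1L, 2L))
  expect_error(nearestEmbedding(matrix(0, 0, 2), c(1, 1)), "empty")
  expect_error(nearestEmbedding(E, c(1, 2, 3)), "codebook width")
})

test_that("train mode quantizes by label, test mode by nearest code", {
  set.seed(1)
  E <- matrix(runif(3 * 5, -1, 1), 3, dimnames = list(c("A", "B", "C"),
                                                      NULL))
  m <- toySVQVAE(E)
  x <- matrix(rnorm(2 * 6), 2)
  fw <- svqvaeForward(m, x, y = c("B", "B"), mode = "train")
  expect_equal(fw$zq, E[c(2, 2), ], ignore_attr = TRUE)  # label lookup,
  # regardless of where z_e falls (regression against plain-VQ behaviour)
  fwt <- svqvaeForward(m, x, mode = "test")
  expect_equal(fwt$zq, E[fwt$k, , drop = FALSE], ignore_attr = TRUE)
  expect_identical(fw$k, fwt$k)          # k reported in both modes
  expect_error(svqvaeForward(m, x, mode = "train"), "labels")
  expect_error(svqvaeForward(m, x, y = c("Z", "A"), mode = "train"),
               "unknown class")
  expect_true(all(abs(fw$reconstruction) <= m@config$outputScale))
})

test_that("loss arithmetic matches hand-computed toy values", {
  # plant an encoder that outputs exactly z_e = (1, 0): zero weights with a
  # head bias of (1, 0)
  E <- rbind(y = c(0, 0), other = c(5, 5))
  m <- toySVQVAE(E, inputDim = 3L, hidden = 2L)
  for (nm in names(m@params)) m@params[[nm]][] <- 0
  m@params[["head.b"]] <- c(1, 0)
  x <- matrix(0, 1, 3)                  # zero profile, zero decoder: l_r = 0
  l <- svqvaeLoss(m, x, "y")
  expect_identical(l$k, 1L)             # nearest code is the class code
  expect_equal(l$reconstruction, 0)
  expect_equal(l$dictionary, 1.0)       # ||(1,0) - (0,0)||^2
  expect_equal(l$commitment, 0.25)      # beta = 0.25
  expect_equal(l$misclassDictionary, 0) # k == y gates the subtracted terms
  expect_equal(l$divergence, 0)
  expect_equal(l$total, 0 + 1 + 0.25)

  # now make the nearest code a *wrong* class: e_k = (1, 0) != e_y = (0, 0)
  E2 <- rbind(y = c(0, 0), other = c(1, 0))
  m2 <- toySVQVAE(E2, inputDim = 3L, hidden = 2L)
  for (nm in names(m2@params)) m2@params[[nm]][] <- 0
  m2@params[["head.b"]] <- c(1, 0)
  l2 <- svqvaeLoss(m2, x, "y")
  expect_identical(l2$k, 2L)
  expect_equal(l2$misclassDictionary, 0)   # ||z_e - e_k||^2 = 0 here
  # shift z_e so the mis-class distance is 0.25 with k still = 2
  m2@params[["head.b"]] <- c(1.5, 0)
  l3 <- svqvaeLoss(m2, x, "y")
  expect_identical(l3$k, 2L)
  expect_equal(l3$dictionary, 2.25)
  expect_equal(l3$misclassDictionary, 0.25)
  expect_equal(l3$divergence, 0.1 * 0.25)
  # the gated terms are subtracted (Eq. sign structure): moving z_e away
  # from the wrong code decreases the loss through these terms
  expect_equal(l3$total,
               l3$reconstruction + 2.25 + 0.25 * 2.25 - 0.25 - 0.025)
})

test_that("loss components are non-negative and totals stay finite", {
  m <- fixtureSVQVAE()
  X <- sampleMatrix(fixtureSimSmall()$data)[1:20, ]
  y <- sampleInfo(fixtureSimSmall()$data)$pcl_label[1:20]
  l <- svqvaeLoss(m, X, y)
  for (nm in c("reconstruction", "dictionary", "commitment",
               "misclassDictionary", "divergence"))
    expect_gte(l[[nm]], 0)
  expect_true(is.finite(l$total))
  lg <- trainingLog(m)
  expect_true(all(is.finite(lg$total)))
})

test_that("straight-through gradients match the finite-difference oracle", {
  set.seed(20)
  E <- matrix(runif(3 * 5, -0.5, 0.5), 3,
              dimnames = list(c("A", "B", "C"), NULL))
  m <- toySVQVAE(E, inputDim = 6L, hidden = 4L, seed = 2L)
  params <- m@params
  cfg <- m@config
  set.seed(5)
  X <- matrix(rnorm(4 * 6), 4); y <- c("A", "B", "C", "A")
  yIdx <- match(y, rownames(E))
  g <- svqvaeGradients(m, X, y)
  k0 <- g$k; mis <- as.numeric(k0 != yIdx); n <- nrow(X)
  fw0 <- svqvaeForward(m, X, y, mode = "train")
  off <- fw0$zq - fw0$ze                 # constant quantization offset
  # straight-through surrogate: reconstruction decoded from z_e + offset,
  # stop-gradient terms held constant
  sur <- function(p) {
    ze <- perturbDGM:::.svqEncode(p, X, cfg)$ze
    dec <- perturbDGM:::.svqDecode(p, ze + off, cfg)
    dy <- ze - E[yIdx, , drop = FALSE]
    dk <- ze - E[k0, , drop = FALSE]
    mean((dec$Xhat - X)^2) + cfg$beta * sum(dy^2) / n -
      cfg$gamma * sum(mis * rowSums(dk^2)) / n
  }
  h <- 1e-6
  for (nm in c("enc1.W", "enc1.b", "head.W", "head.b")) {
    for (i in 1:3) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
      expect_equal(g$grads[[nm]][i], (sur(p1) - sur(p2)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
  # decoder: plain finite differences of the full objective
  full <- function(p, Emat) {
    pp <- c(p, list(E = Emat))
    perturbDGM:::.svqLossGrad(pp, X, yIdx, cfg, wantGrads = FALSE)$total
  }
  for (nm in c("dec1.W", "out.W", "out.b")) {
    for (i in 1:3) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
      expect_equal(g$grads[[nm]][i], (full(p1, E) - full(p2, E)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
  # codebook: only the dictionary and mis-class dictionary terms see E
  fE <- function(Emat) {
    dy <- g$ze - Emat[yIdx, , drop = FALSE]
    dk <- g$ze - Emat[k0, , drop = FALSE]
    sum(dy^2) / n - sum(mis * rowSums(dk^2)) / n
  }
  for (i in seq_len(length(E))) {
    E1 <- E; E1[i] <- E1[i] + h
    E2 <- E; E2[i] <- E2[i] - h
    expect_equal(g$grads[["E"]][i], (fE(E1) - fE(E2)) / (2 * h),
                 tolerance = 1e-4)
  }
  # when z_e = e_y and k = y for the whole batch, e_y receives no gradient
  mz <- toySVQVAE(rbind(a = c(0, 0), b = c(3, 3)), inputDim = 3L,
                  hidden = 2L)
  for (nm in names(mz@params)) mz@params[[nm]][] <- 0
  gz <- svqvaeGradients(mz, matrix(0, 2, 3), c("a", "a"))
  expect_equal(gz$grads[["E"]][1, ], c(0, 0))
})

test_that("training recovers separable classes and their codes", {
  m <- fixtureSVQVAE()
  sim <- fixtureSimSmall()
  lg <- trainingLog(m)
  expect_gt(lg$val_match[nrow(lg)], 0.8)   # chance is 1/8
  X <- sampleMatrix(sim$data)
  lab <- sampleInfo(sim$data)$pcl_label
  fw <- svqvaeForward(m, X, mode = "test")
  expect_gt(mean(classLabels(m)[fw$k] == lab), 0.9)
  cors <- sapply(classLabels(m), function(cl)
    cor(codebook(m)[cl, ], colMeans(fw$ze[lab == cl, , drop = FALSE])))
  expect_true(all(cors >= 0.9))
  # reproducibility of the whole fit
  m2 <- trainSVQVAE(sim$data,
                    svqvaeConfig(epochs = 5L, seed = 7L))
  m3 <- trainSVQVAE(sim$data,
                    svqvaeConfig(epochs = 5L, seed = 7L))
  expect_identical(codebook(m2), codebook(m3))
  # degenerate regularizer-free config still trains
  m4 <- trainSVQVAE(sim$data, svqvaeConfig(epochs = 2L, beta = 0,
                                           gamma = 0, seed = 1L))
  expect_true(all(is.finite(trainingLog(m4)$total)))
})

test_that("class-conditional generation is seeded ancestral sampling", {
  m <- fixtureSVQVAE()
  gen0 <- generateClassConditional(m, "PCL_01", n = 4L, sigma2 = 0,
                                   seed = 2L)
  ref <- decodeCode(m, codebook(m)["PCL_01", ])
  for (i in 1:4)
    expect_equal(sampleMatrix(gen0)[i, ], ref[1, ], ignore_attr = TRUE)
  g1 <- generateClassConditional(m, "PCL_02", n = 10L, seed = 3L)
  g2 <- generateClassConditional(m, "PCL_02", n = 10L, seed = 3L)
  expect_identical(zscores(g1), zscores(g2))
  expect_error(generateClassConditional(m, "PCL_01", n = 0L), "positive")
  expect_error(generateClassConditional(m, "nope", n = 2L), "unknown class")
  # unconditional: classes drawn from the training multinomial
  gu <- generateClassConditional(m, n = 50L, seed = 4L)
  expect_true(all(sampleInfo(gu)$pcl_label %in% classLabels(m)))
  # generated samples sit nearest to real samples of their own class
  gen <- do.call(rbind, lapply(classLabels(m), function(cl)
    sampleMatrix(generateClassConditional(m, cl, n = 25L, seed = 5L))))
  genLab <- rep(classLabels(m), each = 25L)
  nn <- nearestRealNeighbor(gen, sim <- fixtureSimSmall()$data)
  expect_gt(mean(nn$neighbor_label == genLab), 0.7)
})
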