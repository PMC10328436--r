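test_that("view network forward pass composes affine maps and activations", {
  net <- list(W1 = diag(3), b1 = rep(0, 3), W2 = diag(3), b2 = rep(0, 3),
              activation = "identity")
  X <- matrix(rnorm(9), 3, 3)
  expect_equal(forwardView(net, X), X)

  relu <- list(W1 = diag(3), b1 = rep(0, 3), W2 = matrix(1, 2, 3),
               b2 = c(5, -1), activation = "relu")
  Xneg <- matrix(-abs(rnorm(9)) - 1, 3, 3)
  out <- forwardView(relu, Xneg)
  expect_equal(out, matrix(c(5, -1), 2, 3))  # all hidden units killed

  expect_error(forwardView(relu, matrix(0, 2, 3)), "input features")
})

test_that("network backpropagation matches central finite differences", {
  cfg <- viewNetworkConfig(hiddenUnits = 6, outputUnits = 3,
                           activation = "tanh", l1 = 0, l2 = 0)
  set.seed(1)
  net <- initViewNetwork(4, cfg)
  X <- matrix(rnorm(4 * 3), 4, 3)
  Tgt <- matrix(rnorm(3 * 3), 3, 3)
  loss <- function(nn) sum((forwardView(nn, X) - Tgt)^2)
  g <- survGCCA:::.backwardView(net, X, 2 * (forwardView(net, X) - Tgt))
  h <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2")) {
    for (idx in seq_along(net[[nm]])) {
      np <- net; np[[nm]][idx] <- np[[nm]][idx] + h
      nm2 <- net; nm2[[nm]][idx] <- nm2[[nm]][idx] - h
      fd <- (loss(np) - loss(nm2)) / (2 * h)
      expect_lt(abs(fd - g[[nm]][idx]) / max(abs(fd), abs(g[[nm]][idx]), 1e-8),
                1e-5)
    }
  }
})

test_that("gccaSolve matches the dense eigendecomposition oracle", {
  set.seed(21)
  outs <- lapply(1:3, function(v) matrix(rnorm(5 * 20), 5, 20))
  cfg <- gccaConfig(embeddingDim = 2, viewRank = 5, covReg = 1e-6)
  sol <- gccaSolve(outs, cfg = cfg)
  oracle <- denseGccaOracle(outs, r = 2, rho = 1e-6)
  expect_lt(abs(sol@objective - oracle$objective), 1e-8)
  # subspace agreement via principal angles
  expect_lt(max(acos(pmin(svd(sol@G %*% t(oracle$G))$d, 1))), 1e-6)
  expect_equal(sol@eigenvalues, oracle$eigenvalues[1:2], tolerance = 1e-10)
  expect_lt(max(abs(tcrossprod(sol@G) - diag(2))), 1e-6)
})

test_that("gccaSolve honors view weights in objective and solution", {
  set.seed(4)
  outs <- lapply(1:2, function(v) matrix(rnorm(4 * 15), 4, 15))
  w <- c(2, 0.5)
  cfg <- gccaConfig(embeddingDim = 2, viewRank = 4, covReg = 1e-6,
                    viewWeights = w)
  sol <- gccaSolve(outs, cfg = cfg)
  oracle <- denseGccaOracle(outs, r = 2, rho = 1e-6, weights = w)
  expect_lt(abs(sol@objective - oracle$objective), 1e-8)
  expect_equal(sol@objective, sum(w * sol@perViewResiduals), tolerance = 1e-12)
})

test_that("objective is invariant under a common sample permutation", {
  set.seed(5)
  outs <- lapply(1:3, function(v) matrix(rnorm(4 * 18), 4, 18))
  cfg <- gccaConfig(embeddingDim = 3, viewRank = 4)
  perm <- sample(18)
  o1 <- gccaSolve(outs, cfg = cfg)@objective
  o2 <- gccaSolve(lapply(outs, function(Y) Y[, perm]), cfg = cfg)@objective
  expect_lt(abs(o1 - o2), 1e-8)
})

test_that("identical full-rank views are perfectly shared", {
  set.seed(6)
  Y <- matrix(rnorm(4 * 15), 4, 15)
  cfg <- gccaConfig(embeddingDim = 3, viewRank = 4, covReg = 1e-12)
  sol <- gccaSolve(list(Y, Y, Y), cfg = cfg)
  expect_lt(sol@objective, 1e-6)
  expect_true(all(abs(sol@eigenvalues - 3) < 1e-6))
  expect_true(all(sol@eigenvalues <= 3 + 1e-9))
})

test_that("two-view solution recovers classical canonical correlations", {
  set.seed(7)
  Z <- matrix(rnorm(3 * 40), 3, 40)                    # shared structure
  Y1 <- rbind(Z + 0.3 * matrix(rnorm(120), 3, 40), matrix(rnorm(40), 1, 40))
  Y2 <- rbind(0.5 * Z + 0.2 * matrix(rnorm(120), 3, 40))
  cfg <- gccaConfig(embeddingDim = 3, viewRank = 4, covReg = 1e-10)
  sol <- gccaSolve(list(Y1, Y2), cfg = cfg)
  # SVD-based two-view CCA oracle: singular values of Q1^T Q2
  orth <- function(Y) qr.Q(qr(t(Y - rowMeans(Y))))
  rho <- svd(crossprod(orth(Y1), orth(Y2)))$d
  # sharedness eigenvalue of view pair = 1 + canonical correlation
  expect_equal(sol@eigenvalues, 1 + rho[1:3], tolerance = 1e-6)
})

test_that("gradients vanish at a perfectly shared configuration", {
  set.seed(8)
  Y <- matrix(rnorm(3 * 12), 3, 12)
  cfg <- gccaConfig(embeddingDim = 2, viewRank = 3, covReg = 1e-12)
  lg <- gccaLossAndGrads(list(Y, Y), cfg = cfg)
  expect_lt(max(abs(lg$grads[[1]])), 1e-5)
  expect_lt(max(abs(lg$grads[[2]])), 1e-5)
})

test_that("gradient of the solved objective matches finite differences", {
  set.seed(9)
  outs <- lapply(1:2, function(v) matrix(rnorm(4 * 12), 4, 12))
  cfg <- gccaConfig(embeddingDim = 2, viewRank = 4, covReg = 1e-6)
  lg <- gccaLossAndGrads(outs, cfg = cfg)
  h <- 1e-5
  idx <- rbind(c(1, 1, 1), c(1, 3, 7), c(2, 2, 4), c(2, 4, 12), c(1, 2, 9))
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, 1]; i <- idx[k, 2]; j <- idx[k, 3]
    op <- outs; op[[v]][i, j] <- op[[v]][i, j] + h
    om <- outs; om[[v]][i, j] <- om[[v]][i, j] - h
    fd <- (gccaSolve(op, cfg = cfg)@objective -
             gccaSolve(om, cfg = cfg)@objective) / (2 * h)
    g <- lg$grads[[v]][i, j]
    expect_lt(abs(fd - g) / max(abs(fd), abs(g), 1e-8), 1e-4)
  }
})

test_that("doubling a view weight doubles that view's gradient", {
  set.seed(10)
  outs <- lapply(1:2, function(v) matrix(rnorm(3 * 10), 3, 10))
  base <- gccaConfig(embeddingDim = 2, viewRank = 3, viewWeights = c(1, 1))
  dbl <- gccaConfig(embeddingDim = 2, viewRank = 3, viewWeights = c(2, 1))
  g1 <- gccaLossAndGrads(outs, cfg = base)
  # hold G, U fixed from the base solve; recompute the weighted gradient term
  sol <- g1$solution
  Yc <- outs[[1]] - rowMeans(outs[[1]])
  gv <- function(w) {
    Gv <- 2 * w * (sol@U[[1]] %*% (crossprod(sol@U[[1]], Yc) - sol@G))
    Gv - rowMeans(Gv)
  }
  expect_equal(gv(2), 2 * gv(1), tolerance = 1e-12)
})

test_that("a sample seen by a single view leaves other projections intact", {
  set.seed(11)
  Y1 <- matrix(rnorm(6 * 20), 6, 20)
  Y2 <- matrix(rnorm(6 * 20), 6, 20)
  cfg <- gccaConfig(embeddingDim = 2, viewRank = 6)
  base <- gccaSolve(list(Y1, Y2), cfg = cfg)
  # append one sample present only in view 1, at view 1's mean profile
  Y1p <- cbind(Y1, rowMeans(Y1))
  Y2p <- cbind(Y2, 0)
  pres <- rbind(matrix(TRUE, 20, 2), c(TRUE, FALSE))
  ext <- gccaSolve(list(Y1p, Y2p), pres, cfg)
  expect_lt(max(abs(ext@U[[2]] - base@U[[2]])), 1e-6)
  expect_lt(max(abs(ext@G[, 21])), 1e-6)
})

test_that("training is deterministic and its loss decreases steadily", {
  co <- smallPlantedCohort(seed = 2)
  ncf <- viewNetworkConfig(hiddenUnits = 40, outputUnits = 15)
  gcf <- gccaConfig(embeddingDim = 8, viewRank = 15, epochs = 10, seed = 3)
  m1 <- trainDgcca(co@dataset, ncf, gcf)
  m2 <- trainDgcca(co@dataset, ncf, gcf)
  expect_identical(m1@lossHistory, m2@lossHistory)
  expect_identical(m1@networks, m2@networks)
  expect_length(m1@lossHistory, 10L)
  # non-increasing after epoch 2, within 1%
  d <- diff(m1@lossHistory[-1])
  expect_true(all(d <= 0.01 * m1@lossHistory[2]))
})

test_that("embedding covers every sample, including incomplete ones", {
  co <- smallPlantedCohort(seed = 4)
  ncf <- viewNetworkConfig(hiddenUnits = 30, outputUnits = 12)
  gcf <- gccaConfig(embeddingDim = 5, viewRank = 12, epochs = 3, seed = 1)
  m <- trainDgcca(co@dataset, ncf, gcf)
  emb <- embedSamples(m, co@dataset)
  expect_identical(dim(emb), c(150L, 5L))
  expect_identical(rownames(emb), sampleUniverse(co@dataset))
  expect_true(all(is.finite(emb)))
  # r = 1: single unit-norm column
  g1 <- gccaConfig(embeddingDim = 1, viewRank = 12, epochs = 2, seed = 1)
  m1 <- trainDgcca(co@dataset, ncf, g1)
  e1 <- embedSamples(m1, co@dataset)
  expect_identical(ncol(e1), 1L)
  expect_equal(sum(e1^2), 1, tolerance = 1e-8)
})

test_that("duplicating every sample duplicates its embedding row", {
  set.seed(12)
  outs <- lapply(1:2, function(v) matrix(rnorm(4 * 10), 4, 10))
  cfg <- gccaConfig(embeddingDim = 2, viewRank = 4)
  dup <- lapply(outs, function(Y) cbind(Y, Y))
  sol <- gccaSolve(dup, cfg = cfg)
  for (j in 1:10)
    expect_lt(max(abs(sol@G[, j] - sol@G[, j + 10])), 1e-6)
})

test_that("training refuses invalid shapes and degenerate configs", {
  co <- smallPlantedCohort(seed = 5)
  expect_error(gccaSolve(list(matrix(0, 2, 3)), cfg = gccaConfig(embeddingDim = 1, viewRank = 1)),
               "at least 2 views")
  expect_error(gccaSolve(lapply(1:2, function(v) matrix(rnorm(6), 2, 3)),
                         cfg = gccaConfig(embeddingDim = 5, viewRank = 5)),
               "exceeds sample count")
})
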