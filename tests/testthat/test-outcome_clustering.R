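test_that("univariate Cox score test equals the two-group log-rank statistic", {
  # fixed 8-sample fixture, distinct event times, group indicator feature
  time <- c(2, 4, 6, 8, 1, 3, 5, 7)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  group <- c(0, 0, 0, 0, 1, 1, 1, 1)
  surv <- SurvivalTable(paste0("s", 1:8), time, as.integer(event))
  hand <- handLogrank(time, event, group)
  res <- coxUnivariate(group, surv)
  fit <- survival::coxph(survival::Surv(time, event) ~ group, ties = "efron")
  sc <- summary(fit)$sctest
  expect_equal(unname(sc["test"]), hand$chi2, tolerance = 1e-8)
  expect_equal(res$pValue, pchisq(hand$chi2, 1, lower.tail = FALSE),
               tolerance = 1e-8)

  # degenerate: constant feature carries no information
  flat <- coxUnivariate(rep(1, 8), surv)
  expect_identical(flat$pValue, 1)
  expect_false(flat$selected)
})

test_that("embedding filter keeps significant coordinates in order", {
  set.seed(31)
  n <- 120
  surv <- makeSurvival(n, seed = 31, hr = 3, group = rep(0:1, each = n / 2))
  emb <- cbind(matrix(rnorm(n * 4), n, 4), strong = rep(0:1, each = n / 2),
               matrix(rnorm(n * 2), n, 2))
  flt <- filterEmbedding(emb, surv)
  expect_true(5 %in% flt$results$coordinate[flt$results$selected])
  expect_identical(flt$results$coordinate, 1:7)
  expect_identical(ncol(flt$embedding), sum(flt$results$selected))
  # selected columns keep their original relative order
  sel <- flt$results$coordinate[flt$results$selected]
  expect_identical(unname(flt$embedding[, which(sel == 5)]), unname(emb[, 5]))

  # nothing significant halts the pipeline
  calm <- makeSurvival(40, seed = 1)
  set.seed(2)
  expect_error(
    filterEmbedding(matrix(rep(rnorm(40), 2), 40, 2), calm, alpha = 1e-12),
    "alpha")
})

test_that("k-means recovers planted blobs and reports valid diagnostics", {
  set.seed(32)
  X <- rbind(matrix(rnorm(120, 0, 1), ncol = 2),
             matrix(rnorm(120, 10, 1), ncol = 2))
  truth <- rep(1:2, each = 60)
  km <- kmeansFit(X, 2, nInit = 10, maxIter = 200, seed = 1)
  expect_identical(adjRandIndex(clusterLabels(km), truth), 1)
  expect_true(all(table(clusterLabels(km)) > 0))
  expect_gt(km@avgSilhouette, 0.8)

  # more restarts can only improve (never worsen) the best inertia
  i5 <- kmeansFit(X, 3, nInit = 5, maxIter = 200, seed = 7)@inertia
  i20 <- kmeansFit(X, 3, nInit = 20, maxIter = 200, seed = 7)@inertia
  expect_lte(i20, i5 + 1e-9)
})

test_that("k equal to the sample count degenerates gracefully", {
  set.seed(33)
  X <- matrix(rnorm(12), 6, 2)
  expect_warning(km <- kmeansFit(X, 6, nInit = 3, maxIter = 10, seed = 1),
                 "silhouette")
  expect_equal(km@inertia, 0, tolerance = 1e-12)
  expect_true(is.na(km@avgSilhouette))
})

test_that("Calinski-Harabasz matches a hand sum-of-squares computation", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 10, 10, 11, 10, 10, 11),
              ncol = 2, byrow = TRUE)
  labels <- rep(1:2, each = 3)
  # hand computation: per-cluster means, WSS, BSS
  m1 <- colMeans(X[1:3, ]); m2 <- colMeans(X[4:6, ]); mg <- colMeans(X)
  wss <- sum(sweep(X[1:3, ], 2, m1)^2) + sum(sweep(X[4:6, ], 2, m2)^2)
  bss <- 3 * sum((m1 - mg)^2) + 3 * sum((m2 - mg)^2)
  expect_equal(calinskiHarabasz(X, labels), (bss / 1) / (wss / 4))

  ident <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  expect_identical(calinskiHarabasz(ident, labels), Inf)
  expect_error(calinskiHarabasz(X, rep(1, 6)), "2 clusters")
})

test_that("model selection picks the planted number of clusters", {
  set.seed(34)
  X <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 8), ncol = 2),
             matrix(rnorm(100, c(-8, 8)), ncol = 2))
  sel <- selectK(X, 2:6, nInit = 10, maxIter = 200, seed = 1)
  expect_identical(sel$kBest, 3L)
  expect_identical(nrow(sel$diagnostics), 5L)
  expect_identical(sel$diagnostics$k, 2:6)
  expect_true(all(c("avgSilhouette", "chScore", "fracNegativeSilhouette")
                  %in% names(sel$diagnostics)))

  # two blobs: CH decreases beyond k = 2, so 2 wins
  X2 <- rbind(matrix(rnorm(120, 0), ncol = 2), matrix(rnorm(120, 9), ncol = 2))
  sel2 <- selectK(X2, 2:6, nInit = 10, maxIter = 200, seed = 1)
  expect_identical(sel2$kBest, 2L)
  expect_identical(which.max(sel2$diagnostics$chScore), 1L)
})

test_that("log-rank test is exact on the hand fixture and exchangeable", {
  time <- c(3, 5, 7, 9, 11, 2, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  group <- rep(1:2, each = 5)
  surv <- SurvivalTable(paste0("s", 1:10), time, as.integer(event))
  cmp <- logrankGroups(group, surv)
  hand <- handLogrank(time, event, group)
  expect_equal(cmp@chi2, hand$chi2, tolerance = 1e-8)
  expect_identical(cmp@df, 1L)
  expect_equal(cmp@pValue, pchisq(hand$chi2, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical time/event multisets in both groups: no separation
  t2 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e2 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  s2 <- SurvivalTable(paste0("x", 1:8), t2, as.integer(e2))
  same <- logrankGroups(rep(1:2, each = 4), s2)
  expect_equal(same@chi2, 0, tolerance = 1e-10)
  expect_equal(same@pValue, 1, tolerance = 1e-10)

  # relabeling invariance and df contract
  three <- logrankGroups(c(1, 1, 1, 2, 2, 2, 3, 3), s2)
  expect_identical(three@df, 2L)
  relab <- logrankGroups(c(3, 3, 3, 1, 1, 1, 2, 2), s2)
  expect_equal(three@pValue, relab@pValue, tolerance = 1e-12)
})

test_that("Kaplan-Meier equals the empirical survival function when uncensored", {
  time <- c(1, 2, 2, 3, 5, 8)
  surv <- SurvivalTable(paste0("s", 1:6), time, rep(1L, 6))
  cmp <- logrankGroups(rep(1:2, 3), surv)
  km <- cmp@kmCurves
  for (g in unique(km$group)) {
    sub <- km[km$group == g, ]
    tg <- time[rep(1:2, 3) == g]
    emp <- vapply(sub$time, function(t0) mean(tg > t0), numeric(1))
    expect_equal(sub$survival, emp, tolerance = 1e-12)
  }
  expect_true(all(diff(km$survival[km$group == km$group[1]]) <= 1e-12))
})
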