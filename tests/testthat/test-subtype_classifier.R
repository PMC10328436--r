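test_that("median scaling stores medians and post-centering moments", {
  x <- matrix(c(1, 2, 9,  5, 5, 5,  0, 4, 2), 3, 3,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  sc <- fitScaler(x)
  expect_equal(unname(sc@center), c(2, 5, 2))
  expect_equal(unname(applyScaler(sc, x)[, "a"]), c(-1, 0, 7))
  expect_true(sc@constant["b" == sc@featureIds])
  expect_false(sc@constant["a" == sc@featureIds])

  centered <- sweep(x, 2, apply(x, 2, median))
  sc2 <- fitScaler(centered)
  expect_equal(unname(applyScaler(sc2, centered)), unname(centered))

  # divide-by-median variant
  scd <- fitScaler(x, method = "divide")
  expect_equal(unname(applyScaler(scd, x)[, "a"]), c(0.5, 1, 4.5))
})

test_that("external standardization uses the training moments", {
  sc <- new("ScalerModel", featureIds = "g", center = 0, mean = 2, sd = 2,
            constant = FALSE)
  ext <- matrix(6, 1, 1, dimnames = list("e1", "g"))
  expect_equal(unname(standardizeExternal(ext, sc)[1, 1]), 2)

  # identical external reproduces the training z-scores
  set.seed(41)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  scl <- fitScaler(x)
  z <- standardizeExternal(x, scl)
  zm <- scale(sweep(x, 2, apply(x, 2, median)))
  expect_equal(unname(z), unname(zm[, ]), tolerance = 1e-12)

  expect_error(standardizeExternal(matrix(1, 1, 1, dimnames = list("s", "zz")),
                                   scl), "unknown")
  # constant training feature passes through centered only
  xc <- cbind(x, k = 1)
  scc <- fitScaler(xc)
  expect_message(zc <- standardizeExternal(xc, scc), "zero-spread")
  expect_equal(unname(zc[, "k"]), rep(0, 20))
})

test_that("equal-frequency bins split distinct training values evenly", {
  x <- matrix(1:10, 10, 1, dimnames = list(NULL, "f"))
  bm <- fitBins(x, 5)
  b <- applyBins(bm, x)
  expect_identical(as.integer(table(b)), rep(2L, 5))
  expect_identical(unname(b[3, 1]), 2L)
  expect_identical(unname(b[1, 1]), 1L)
  expect_identical(unname(b[10, 1]), 5L)

  # clamping outside the training range
  ext <- matrix(c(-100, 100), 2, 1, dimnames = list(NULL, "f"))
  expect_identical(unname(applyBins(bm, ext)[, 1]), c(1L, 5L))

  # constant feature collapses to a single effective bin
  const <- matrix(7, 10, 1, dimnames = list(NULL, "f"))
  bc <- applyBins(fitBins(const, 5), const)
  expect_true(all(bc >= 1))
  expect_identical(length(unique(as.vector(bc))), 1L)

  expect_error(fitBins(x, 11), "exceeds")
  expect_error(applyBins(bm, matrix(NA_real_, 1, 1,
                                    dimnames = list(NULL, "f"))),
               "non-finite")
})

test_that("bin assignments depend on ranks only", {
  set.seed(42)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  b0 <- applyBins(fitBins(x, 8), x)
  # strictly increasing per-feature transforms leave training bins unchanged
  warped <- cbind(exp(x[, 1]), x[, 2]^3 + 2 * x[, 2], atan(x[, 3]),
                  5 * x[, 4] - 7)
  colnames(warped) <- colnames(x)
  b1 <- applyBins(fitBins(warped, 8), warped)
  expect_identical(b0, b1)
  # purity: repeated application is identical
  expect_identical(applyBins(fitBins(x, 8), x), b0)
})

test_that("RFE ranks a perfectly informative feature first", {
  set.seed(43)
  n <- 120
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(NULL, paste0("f", 1:100)))
  x[, 17] <- as.integer(y) + rnorm(n, sd = 0.05)
  fs <- rfRfeSelect(x, y, folds = 5, repeats = 2, numTrees = 150, seed = 1)
  expect_identical(fs@ranking[1], "f17")
  expect_lte(fs@chosenN, 10L)
  expect_true("f17" %in% fs@chosenFeatures)
  expect_gte(max(fs@cvCurve$meanAccuracy), 0.95)
  expect_true(all(diff(fs@cvCurve$size) > 0))
})

test_that("RFE accuracy stays near chance on pure noise", {
  set.seed(44)
  n <- 90
  y <- factor(rep(c("A", "B", "C"), each = n / 3))
  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("f", 1:40)))
  fs <- rfRfeSelect(x, y, folds = 5, repeats = 2, numTrees = 100, seed = 2)
  expect_true(all(abs(fs@cvCurve$meanAccuracy - 1 / 3) < 0.15))
})

test_that("tuned boosted trees separate a separable toy and stay honest on noise", {
  set.seed(45)
  n <- 200
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(ifelse(x[, 1] > 0, "A", "B"))
  clf <- tuneTrainClassifier(x, y, folds = 5, budget = 6, seed = 1)
  expect_gte(clf@cvAccuracy, 0.95)
  expect_gte(clf@cvAuc, 0.95)

  yperm <- factor(sample(as.character(y)))
  nul <- tuneTrainClassifier(x, yperm, folds = 5, budget = 4, seed = 1)
  expect_lt(abs(nul@cvAccuracy - 0.5), 0.15)

  expect_error(tuneTrainClassifier(x, y, budget = 0), "budget")
})

test_that("the full classifier pipeline is deterministic given a seed", {
  set.seed(46)
  n <- 80
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(paste0("s", 1:n),
                                                    paste0("f", 1:20)))
  y <- factor(ifelse(x[, 3] > 0, "A", "B"))
  run <- function() {
    sc <- fitScaler(x); z <- standardizeExternal(x, sc)
    bn <- fitBins(z, 10); b <- applyBins(bn, z)
    fs <- rfRfeSelect(b, y, folds = 4, repeats = 2, numTrees = 80, seed = 9)
    clf <- tuneTrainClassifier(b[, fs@chosenFeatures, drop = FALSE], y,
                               folds = 4, budget = 5, seed = 9,
                               scaler = sc, bins = bn)
    list(fs = fs, clf = clf, pred = predictSubtypes(clf, x))
  }
  a <- run(); b2 <- run()
  expect_identical(a$fs@chosenFeatures, b2$fs@chosenFeatures)
  expect_identical(a$fs@cvCurve, b2$fs@cvCurve)
  expect_identical(a$clf@params, b2$clf@params)
  expect_identical(a$pred, b2$pred)
})

test_that("prediction validates features and handles empty cohorts", {
  set.seed(47)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(paste0("s", 1:50),
                                                 paste0("f", 1:4)))
  y <- factor(ifelse(x[, 1] > 0, "A", "B"))
  sc <- fitScaler(x); z <- standardizeExternal(x, sc)
  bn <- fitBins(z, 5)
  clf <- tuneTrainClassifier(applyBins(bn, z), y, folds = 4, budget = 3,
                             seed = 1, scaler = sc, bins = bn)
  empty <- x[0, , drop = FALSE]
  expect_identical(nrow(predictSubtypes(clf, empty)), 0L)
  expect_error(predictSubtypes(clf, x[, 1:2]), "f3")
})

test_that("feature intersection preserves training order", {
  expect_error(intersectFeatures(c("a", "b"), c("c", "d")), "common")
  expect_identical(intersectFeatures(c("a", "b"), c("b", "a", "z")),
                   c("a", "b"))
  train <- paste0("g", 1:100)
  ext <- sample(paste0("g", 4:100))
  expect_identical(intersectFeatures(train, ext), paste0("g", 4:100))
  expect_identical(length(intersectFeatures(train, ext)), 97L)
})
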