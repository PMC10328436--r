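## Per-omics subtype classifiers that transfer across cohorts and platforms:
## median scaling, training-moment standardization, equal-frequency binning
## with training-bin transfer, RF recursive feature elimination, and boosted
## trees tuned by sequential model-based (Bayesian) optimization.

#' Fit a per-feature scaler: median centering plus post-centering moments
#'
#' Median scaling subtracts the per-feature training median. The mean and
#' standard deviation of the centered training matrix are stored so external
#' cohorts can later be standardized to the training moments (see
#' [standardizeExternal()]). Zero-spread features are flagged.
#'
#' @param x numeric matrix, samples x features (no missing values), or an
#'   [OmicsView-class] (transposed internally).
#' @param method "center" subtracts the training median (default); "divide"
#'   divides by it (features with median 0 are left unscaled, with a
#'   message).
#' @return a [ScalerModel-class].
#' @export
fitScaler <- function(x, method = c("center", "divide")) {
  method <- match.arg(method)
  if (is(x, "OmicsView")) {
    if (any(x@missingMask)) stop("scaler requires a fully observed view")
    x <- t(x@values)
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  med <- apply(x, 2, median)
  scaled <- .medianScale(x, med, method)
  mu <- colMeans(scaled)
  s <- apply(scaled, 2, sd)
  new("ScalerModel", featureIds = colnames(x), center = med, method = method,
      mean = mu, sd = s, constant = s == 0)
}

.medianScale <- function(x, med, method) {
  if (method == "divide") {
    zero <- med == 0
    if (any(zero)) {
      message(sum(zero), " feature(s) with median 0 left unscaled")
      med[zero] <- 1
    }
    sweep(x, 2, med, "/")
  } else {
    sweep(x, 2, med, "-")
  }
}

#' Apply the training median scaling to a matrix
#' @param scaler a [ScalerModel-class].
#' @param x samples x features matrix; features must be known to the scaler.
#' @return median-scaled matrix.
#' @export
applyScaler <- function(scaler, x) {
  unknown <- setdiff(colnames(x), scaler@featureIds)
  if (length(unknown))
    stop("feature(s) unknown to the scaler: ", paste(unknown, collapse = ", "))
  idx <- match(colnames(x), scaler@featureIds)
  method <- if (length(scaler@method)) scaler@method else "center"
  suppressMessages(.medianScale(x, scaler@center[idx], method))
}

#' Standardize an external cohort to the training moments
#'
#' Applies the training median centering, then (value - training mean) /
#' training sd per feature. Features with zero training spread pass through
#' centered only (logged via message).
#'
#' @param x external samples x features matrix.
#' @param scaler a [ScalerModel-class] fitted on training data.
#' @return standardized matrix.
#' @export
standardizeExternal <- function(x, scaler) {
  centered <- applyScaler(scaler, x)
  idx <- match(colnames(x), scaler@featureIds)
  mu <- scaler@mean[idx]; s <- scaler@sd[idx]
  if (any(s == 0)) {
    message(sum(s == 0),
            " zero-spread training feature(s) passed through centered only")
    s[s == 0] <- 1
  }
  sweep(sweep(centered, 2, mu, "-"), 2, s, "/")
}

#' Learn per-feature equal-frequency bin edges on training data
#'
#' Interior cut points are placed at the i/B quantiles (i = 1..B-1,
#' linear-interpolation quantile definition) of each feature's training
#' values; with distinct values the training bin occupancies differ by at
#' most one. Duplicate edges (heavy ties) are merged, yielding fewer
#' effective bins for that feature.
#'
#' @param x scaled training matrix, samples x features.
#' @param nBins requested number of bins B >= 2 (30 and 15 are typical
#'   choices for finer/coarser discretization).
#' @return a [BinningModel-class].
#' @export
fitBins <- function(x, nBins = 30L) {
  stopifnot(is.matrix(x), nBins >= 2)
  if (nBins > nrow(x))
    stop("nBins (", nBins, ") exceeds the number of training samples (",
         nrow(x), ")")
  probs <- seq_len(nBins - 1L) / nBins
  edges <- lapply(seq_len(ncol(x)), function(j) {
    e <- unique(unname(quantile(x[, j], probs, type = 7)))
    e
  })
  names(edges) <- colnames(x)
  new("BinningModel", nBins = as.integer(nBins), edges = edges)
}

#' Assign values to the training bins
#'
#' Values below the first edge map to bin 1; values at or above the last
#' edge map to the top bin; interior bins are the half-open intervals
#' \[edge_(i-1), edge_i). External samples are therefore placed into the bins
#' formed by the training data, never re-binned.
#'
#' @param model a [BinningModel-class].
#' @param x samples x features matrix; all features must be in the model.
#' @return integer matrix of bin indices.
#' @export
applyBins <- function(model, x) {
  unknown <- setdiff(colnames(x), names(model@edges))
  if (length(unknown))
    stop("feature(s) without binning edges: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(x))) stop("non-finite value passed to applyBins")
  out <- x
  for (j in colnames(x))
    out[, j] <- findInterval(x[, j], model@edges[[j]]) + 1L
  storage.mode(out) <- "integer"
  out
}

# deterministic stratified fold assignment
.stratifiedFolds <- function(y, folds) {
  idx <- integer(length(y))
  for (cl in levels(y)) {
    members <- sample(which(y == cl))
    idx[members] <- rep_len(seq_len(folds), length(members))
  }
  idx
}

#' Random-forest recursive feature elimination with repeated CV
#'
#' Within each fold of a repeated stratified cross-validation, features are
#' ranked by random-forest impurity importance on the training part, and
#' nested subsets of decreasing size are evaluated on the held-out part.
#' The chosen size is the smallest whose mean accuracy is within one
#' standard error (the resampling standard deviation of the best size's
#' accuracy divided by the square root of the number of resamples) of the
#' best mean accuracy -- the classical one-standard-error rule, which makes
#' the usual visual "elbow" pick mechanical and reproducible. The returned
#' ranking comes from a full-data forest.
#'
#' @param x binned feature matrix, samples x features.
#' @param y class labels (factor or coercible).
#' @param sizes candidate feature counts (default: halving grid from p).
#' @param folds CV folds (default 10).
#' @param repeats CV repeats (default 10).
#' @param numTrees trees per forest (default 300).
#' @param seed integer seed.
#' @return a [FeatureSelection-class].
#' @export
rfRfeSelect <- function(x, y, sizes = NULL, folds = 10L, repeats = 10L,
                        numTrees = 300L, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  if (min(table(y)) < folds)
    stop("folds (", folds, ") exceeds the smallest class size")
  p <- ncol(x)
  if (is.null(sizes)) {
    sizes <- p
    while (tail(sizes, 1) > 1L) sizes <- c(sizes, ceiling(tail(sizes, 1) / 2))
    sizes <- sort(unique(sizes))
  }
  sizes <- sort(unique(pmin(sizes, p)))
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  df <- as.data.frame(x)
  acc <- matrix(NA_real_, folds * repeats, length(sizes))
  row <- 0L
  for (rep_ in seq_len(repeats)) {
    foldId <- .stratifiedFolds(y, folds)
    for (f in seq_len(folds)) {
      row <- row + 1L
      tr <- foldId != f
      fit <- ranger::ranger(x = df[tr, , drop = FALSE], y = y[tr],
                            num.trees = numTrees, importance = "impurity",
                            seed = seed + 1000L * rep_ + f, num.threads = 1L)
      ranked <- names(sort(fit$variable.importance, decreasing = TRUE))
      for (si in seq_along(sizes)) {
        top <- ranked[seq_len(sizes[si])]
        sub <- ranger::ranger(x = df[tr, top, drop = FALSE], y = y[tr],
                              num.trees = numTrees,
                              seed = seed + 7L * row + si, num.threads = 1L)
        pred <- predict(sub, df[!tr, top, drop = FALSE],
                        num.threads = 1L)$predictions
        acc[row, si] <- mean(pred == y[!tr])
      }
    }
  }
  curve <- data.frame(size = sizes, meanAccuracy = colMeans(acc),
                      sdAccuracy = apply(acc, 2, sd))
  curve$seAccuracy <- curve$sdAccuracy / sqrt(nrow(acc))
  bestIdx <- which.max(curve$meanAccuracy)
  cut <- curve$meanAccuracy[bestIdx] - curve$seAccuracy[bestIdx]
  chosenN <- min(curve$size[curve$meanAccuracy >= cut])
  full <- ranger::ranger(x = df, y = y, num.trees = numTrees,
                         importance = "impurity", seed = seed,
                         num.threads = 1L)
  ranking <- names(sort(full$variable.importance, decreasing = TRUE))
  new("FeatureSelection", ranking = ranking, cvCurve = curve,
      chosenN = as.integer(chosenN),
      chosenFeatures = ranking[seq_len(chosenN)])
}

## ---- sequential model-based (Bayesian) hyperparameter search ----

.xgbSpace <- list(
  eta              = c(log(0.01), log(0.3)),   # log scale
  max_depth        = c(2, 8),                  # integer
  nrounds          = c(50, 300),               # integer
  subsample        = c(0.5, 1),
  colsample_bytree = c(0.5, 1),
  min_child_weight = c(1, 10))

.decodeParams <- function(u) {
  sp <- .xgbSpace
  dec <- function(name) sp[[name]][1] + u[[name]] * diff(sp[[name]])
  list(eta = exp(dec("eta")),
       max_depth = as.integer(round(dec("max_depth"))),
       nrounds = as.integer(round(dec("nrounds"))),
       subsample = dec("subsample"),
       colsample_bytree = dec("colsample_bytree"),
       min_child_weight = dec("min_child_weight"))
}

# Gaussian-process expected improvement on the unit hypercube.
.gpExpectedImprovement <- function(Xobs, yobs, Xcand, lengthscale = 0.3,
                                   noise = 1e-4) {
  kfun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  mu0 <- mean(yobs)
  K <- kfun(Xobs, Xobs) + diag(noise, nrow(Xobs))
  Ks <- kfun(Xcand, Xobs)
  alpha <- solve(K, yobs - mu0)
  mu <- mu0 + Ks %*% alpha
  vpred <- pmax(1 - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
  sdev <- sqrt(vpred)
  best <- max(yobs)
  z <- (mu - best) / sdev
  (mu - best) * pnorm(z) + sdev * dnorm(z)
}

.xgbCv <- function(x, y, params, folds, seed) {
  k <- nlevels(y)
  yNum <- as.integer(y) - 1L
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  foldId <- .stratifiedFolds(y, folds)
  prob <- matrix(NA_real_, length(y), k)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    booster <- .xgbFit(x[tr, , drop = FALSE], yNum[tr], k, params,
                       seed + f)
    prob[!tr, ] <- .xgbPredictProb(booster, x[!tr, , drop = FALSE], k)
  }
  pred <- max.col(prob, ties.method = "first")
  list(accuracy = mean(pred == as.integer(y)), prob = prob)
}

.xgbFit <- function(x, yNum, k, params, seed) {
  common <- list(max_depth = params$max_depth, eta = params$eta,
                 subsample = params$subsample,
                 colsample_bytree = params$colsample_bytree,
                 min_child_weight = params$min_child_weight,
                 nthread = 1L, seed = seed)
  if (k == 2L) {
    common$objective <- "binary:logistic"
  } else {
    common$objective <- "multi:softprob"
    common$num_class <- k
  }
  xgboost::xgb.train(params = common,
                     data = xgboost::xgb.DMatrix(x, label = yNum),
                     nrounds = params$nrounds, verbose = 0)
}

.xgbPredictProb <- function(booster, x, k) {
  pr <- predict(booster, xgboost::xgb.DMatrix(x))
  if (k == 2L) cbind(1 - pr, pr) else matrix(pr, ncol = k, byrow = TRUE)
}

# one-vs-rest macro AUC (plain binary AUC when k = 2)
.macroAuc <- function(y, prob) {
  k <- nlevels(y)
  aucs <- vapply(seq_len(k), function(j) {
    resp <- as.integer(as.integer(y) == j)
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, j], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  if (k == 2L) aucs[2] else mean(aucs, na.rm = TRUE)
}

#' Tune and train a boosted-tree subtype classifier
#'
#' Sequential model-based (Bayesian) optimization over a fixed hyperparameter
#' space (learning rate, tree depth, tree count, row/column subsampling,
#' minimum child weight): a Latin-hypercube initial design followed by
#' Gaussian-process expected-improvement proposals, each configuration scored
#' by mean stratified k-fold cross-validated accuracy. The best configuration
#' is refit on all data; CV accuracy and AUC (one-vs-rest macro for more than
#' two classes) are recorded.
#'
#' @param x binned feature matrix, samples x features (the selected features).
#' @param y subtype labels.
#' @param folds CV folds (default 10).
#' @param budget total configurations evaluated (default 50).
#' @param seed integer seed.
#' @param scaler,bins optional preprocessing artifacts stored on the model so
#'   external cohorts can be preprocessed identically.
#' @return a [SubtypeClassifier-class].
#' @export
tuneTrainClassifier <- function(x, y, folds = 10L, budget = 50L, seed = 1L,
                                scaler = NULL, bins = NULL) {
  if (budget < 1L) stop("budget must be >= 1")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  x <- as.matrix(x); storage.mode(x) <- "double"
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  dims <- names(.xgbSpace)
  nInit <- min(max(5L, budget %/% 3L), budget)
  design <- lhs::randomLHS(nInit, length(dims))
  colnames(design) <- dims
  Xobs <- design
  yobs <- numeric(0)
  evalRow <- function(u) {
    params <- .decodeParams(as.list(u))
    .xgbCv(x, y, params, folds, seed)$accuracy
  }
  for (i in seq_len(nInit)) yobs[i] <- evalRow(Xobs[i, ])
  while (nrow(Xobs) < budget) {
    cand <- matrix(runif(500 * length(dims)), ncol = length(dims),
                   dimnames = list(NULL, dims))
    ei <- .gpExpectedImprovement(Xobs, yobs, cand)
    nxt <- cand[which.max(ei), , drop = FALSE]
    Xobs <- rbind(Xobs, nxt)
    yobs <- c(yobs, evalRow(nxt[1, ]))
  }
  best <- .decodeParams(as.list(Xobs[which.max(yobs), ]))
  cvFinal <- .xgbCv(x, y, best, folds, seed)
  auc <- .macroAuc(y, cvFinal$prob)
  booster <- .xgbFit(x, as.integer(y) - 1L, nlevels(y), best, seed)
  new("SubtypeClassifier", features = colnames(x),
      boosterRaw = xgboost::xgb.save.raw(booster), params = best,
      classLevels = levels(y), cvAccuracy = cvFinal$accuracy, cvAuc = auc,
      scaler = if (is.null(scaler)) new("ScalerModel") else scaler,
      bins = if (is.null(bins)) new("BinningModel", nBins = 2L, edges = list())
             else bins)
}

#' Common features between a training and an external view
#'
#' Set intersection, returned in training order; downstream feature selection
#' and classifier training are restricted to this set so external cohorts can
#' be scored.
#'
#' @param training,external [OmicsView-class] objects (or feature id vectors).
#' @return character vector of common feature ids.
#' @export
intersectFeatures <- function(training, external) {
  tf <- if (is(training, "OmicsView")) featureIds(training) else training
  ef <- if (is(external, "OmicsView")) featureIds(external) else external
  common <- tf[tf %in% ef]
  if (length(common) == 0L) stop("no features in common")
  common
}

#' Predict subtypes for an external cohort
#'
#' Applies the stored preprocessing chain exactly as at training time:
#' median centering, standardization to training moments, assignment to the
#' training bins, then ensemble prediction. Deterministic given the model.
#'
#' @param model a [SubtypeClassifier-class].
#' @param external an [OmicsView-class] or samples x features matrix covering
#'   all selected features.
#' @return data.frame: sample_id, subtype, plus one score column per class.
#' @export
predictSubtypes <- function(model, external) {
  x <- if (is(external, "OmicsView")) t(external@values) else as.matrix(external)
  missingF <- setdiff(model@features, colnames(x))
  if (length(missingF))
    stop("external cohort lacks selected feature(s): ",
         paste(missingF, collapse = ", "))
  k <- length(model@classLevels)
  if (nrow(x) == 0L)
    return(data.frame(sample_id = character(0), subtype = character(0)))
  x <- x[, model@features, drop = FALSE]
  z <- standardizeExternal(x, model@scaler)
  b <- applyBins(model@bins, z)
  storage.mode(b) <- "double"
  booster <- xgboost::xgb.load.raw(model@boosterRaw)
  prob <- .xgbPredictProb(booster, b, k)
  colnames(prob) <- paste0("score_", model@classLevels)
  data.frame(sample_id = rownames(x),
             subtype = model@classLevels[max.col(prob, ties.method = "first")],
             prob, row.names = NULL)
}

#' @importFrom stats pnorm dnorm
#' @importFrom utils tail
NULL
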