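## Outcome-guided clustering of the shared representation: univariate Cox-PH
## filtering, k-means with many restarts, CH/silhouette model selection, and
## log-rank / Kaplan-Meier quantification of the prognostic separation.

#' Univariate Cox proportional-hazards fit for one feature
#'
#' Fits hazard h0(t) exp(beta x) by partial likelihood (Efron tie handling)
#' and reports the score-test p-value for beta = 0; for a binary group
#' indicator the score test is exactly the two-group log-rank statistic.
#'
#' @param feature numeric vector, one value per sample (aligned to survival).
#' @param survival a [SurvivalTable-class].
#' @param alpha significance threshold used for the \code{selected} flag
#'   (default 0.05).
#' @return data.frame row: beta, pValue, selected.
#' @export
coxUnivariate <- function(feature, survival, alpha = 0.05) {
  stopifnot(length(feature) == length(survival@sampleIds),
            all(is.finite(feature)))
  if (sum(survival@event) < 2L)
    stop("need at least 2 observed events for a Cox fit")
  if (var(feature) == 0)
    return(data.frame(beta = 0, pValue = 1, selected = FALSE))
  fit <- survival::coxph(
    survival::Surv(survival@time, survival@event) ~ feature,
    ties = "efron", control = survival::coxph.control(iter.max = 100))
  if (fit$iter >= 100)
    stop("Cox fit failed to converge within 100 iterations")
  sc <- summary(fit)$sctest
  data.frame(beta = unname(coef(fit)), pValue = unname(sc["pvalue"]),
             selected = unname(sc["pvalue"]) < alpha)
}

#' Filter embedding coordinates by univariate Cox-PH significance
#'
#' Each embedding coordinate is tested as the sole covariate of a univariate
#' Cox model; coordinates with score-test p below \code{alpha} are kept, in
#' their original order.
#'
#' @param embedding N x r matrix (rows = samples, aligned to survival).
#' @param survival a [SurvivalTable-class].
#' @param alpha per-coordinate threshold (default 0.05).
#' @param adjust optional multiple-testing correction applied to the
#'   p-values before thresholding ("none", default, or "BH").
#' @return list: \code{embedding} (N x p filtered matrix), \code{results}
#'   (data.frame: coordinate, beta, pValue, selected).
#' @export
filterEmbedding <- function(embedding, survival, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1,
            nrow(embedding) == length(survival@sampleIds))
  res <- do.call(rbind, lapply(seq_len(ncol(embedding)), function(j)
    coxUnivariate(embedding[, j], survival, alpha)))
  res <- cbind(coordinate = seq_len(ncol(embedding)), res)
  p <- if (adjust == "BH") p.adjust(res$pValue, "BH") else res$pValue
  res$selected <- p < alpha
  if (!any(res$selected))
    stop("no embedding coordinate passed the Cox filter at alpha = ", alpha,
         "; review alpha or the upstream representation")
  list(embedding = embedding[, res$selected, drop = FALSE], results = res)
}

# One Lloyd run from given initial centroids; reseeds a centroid that goes
# empty at the sample farthest from its assigned centroid.
.lloyd <- function(X, centers, maxIter) {
  N <- nrow(X); k <- nrow(centers)
  labels <- integer(N); inertia <- Inf
  for (it in seq_len(maxIter)) {
    D <- vapply(seq_len(k), function(j)
      rowSums(sweep(X, 2, centers[j, ], "-")^2), numeric(N))
    newLabels <- max.col(-D, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(newLabels))
    if (length(empty)) {
      d_assigned <- D[cbind(seq_len(N), newLabels)]
      for (j in empty) {
        far <- which.max(d_assigned)
        centers[j, ] <- X[far, ]
        newLabels[far] <- j
        D[far, j] <- 0
        d_assigned[far] <- 0
      }
    }
    inertia <- sum(D[cbind(seq_len(N), newLabels)])
    converged <- identical(newLabels, labels)
    labels <- newLabels
    if (converged) break
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
  }
  list(centers = centers, labels = labels, inertia = inertia)
}

#' k-means with many random restarts and internal validation indices
#'
#' Lloyd's algorithm with uniform random data-point initialization, keeping
#' the best of \code{nInit} restarts by within-cluster sum of squares; a
#' centroid left empty during iteration is reseeded at the sample farthest
#' from its current centroid. Defaults (100 restarts, 2000 iterations) match
#' the reference configuration. Silhouette widths and the Calinski-Harabasz
#' score are computed on the same matrix.
#'
#' @param X N x p numeric matrix.
#' @param k number of clusters (2 <= k <= N).
#' @param nInit number of random restarts (default 100).
#' @param maxIter Lloyd iterations per restart (default 2000).
#' @param seed integer seed controlling all restarts.
#' @return a [ClusterModel-class].
#' @export
kmeansFit <- function(X, k, nInit = 100L, maxIter = 2000L, seed = 1L) {
  X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(k >= 2, k <= N, ncol(X) >= 1)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(nInit)) {
    centers <- X[sample.int(N, k), , drop = FALSE]
    run <- .lloyd(X, centers, maxIter)
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  if (k < N) {
    sil <- cluster::silhouette(best$labels, dist(X))
    silw <- sil[, "sil_width"]
    avg <- mean(silw)
  } else {
    warning("k equals the number of samples; silhouette undefined")
    silw <- rep(NA_real_, N)
    avg <- NA_real_
  }
  ch <- if (k < N) calinskiHarabasz(X, best$labels) else NA_real_
  new("ClusterModel", k = as.integer(k), centroids = best$centers,
      labels = as.integer(best$labels), inertia = best$inertia,
      avgSilhouette = avg, chScore = ch, perSampleSilhouette = silw)
}

#' Calinski-Harabasz score
#'
#' (between-cluster SS / (k-1)) / (within-cluster SS / (N-k)). Perfectly
#' separated zero-variance clusters yield +Inf.
#'
#' @param X N x p matrix.
#' @param labels integer cluster labels with >= 2 nonempty clusters.
#' @return nonnegative real (possibly Inf).
#' @export
calinskiHarabasz <- function(X, labels) {
  X <- as.matrix(X)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L) stop("Calinski-Harabasz requires >= 2 clusters")
  N <- nrow(X)
  grand <- colMeans(X)
  wss <- 0; bss <- 0
  for (g in ids) {
    Xg <- X[labels == g, , drop = FALSE]
    mu <- colMeans(Xg)
    wss <- wss + sum(sweep(Xg, 2, mu, "-")^2)
    bss <- bss + nrow(Xg) * sum((mu - grand)^2)
  }
  if (wss == 0) return(Inf)
  (bss / (k - 1)) / (wss / (N - k))
}

#' Choose the number of clusters by Calinski-Harabasz with silhouette tie-break
#'
#' Fits k-means for every k in \code{kRange} and selects the k maximizing the
#' Calinski-Harabasz score; ties go to the higher average silhouette, then to
#' the smaller k. The diagnostics table also reports the fraction of samples
#' with negative silhouette width per k, making the usual visual silhouette
#' inspection mechanical.
#'
#' @param X N x p matrix.
#' @param kRange candidate cluster counts (default 2:6).
#' @param nInit,maxIter,seed passed to [kmeansFit()].
#' @return list: \code{kBest}, \code{diagnostics} (one row per k:
#'   k, inertia, avgSilhouette, chScore, fracNegativeSilhouette),
#'   \code{models} (the fitted [ClusterModel-class] per k).
#' @export
selectK <- function(X, kRange = 2:6, nInit = 100L, maxIter = 2000L,
                    seed = 1L) {
  stopifnot(max(kRange) < nrow(X))
  models <- lapply(kRange, function(k)
    kmeansFit(X, k, nInit = nInit, maxIter = maxIter, seed = seed + k))
  diag <- data.frame(
    k = kRange,
    inertia = vapply(models, function(m) m@inertia, numeric(1)),
    avgSilhouette = vapply(models, function(m) m@avgSilhouette, numeric(1)),
    chScore = vapply(models, function(m) m@chScore, numeric(1)),
    fracNegativeSilhouette = vapply(models, function(m)
      mean(m@perSampleSilhouette < 0), numeric(1)))
  ord <- order(-diag$chScore, -diag$avgSilhouette, diag$k)
  kBest <- diag$k[ord[1]]
  list(kBest = kBest, diagnostics = diag,
       models = setNames(models, paste0("k", kRange)))
}

#' k-group log-rank test with Kaplan-Meier curves
#'
#' Chi-square log-rank statistic on k-1 degrees of freedom comparing observed
#' with expected event counts across groups, plus per-group product-limit
#' survival curves with at-risk and event counts at each event time.
#'
#' @param labels group label per sample (aligned to survival).
#' @param survival a [SurvivalTable-class].
#' @return a [SurvivalComparison-class].
#' @export
logrankGroups <- function(labels, survival) {
  stopifnot(length(labels) == length(survival@sampleIds))
  grp <- factor(labels)
  if (nlevels(grp) < 2L) stop("need at least 2 nonempty groups")
  if (sum(survival@event) < 1L) stop("need at least one observed event")
  sd_ <- survival::survdiff(
    survival::Surv(survival@time, survival@event) ~ grp)
  df <- nlevels(grp) - 1L
  chi2 <- unname(sd_$chisq)
  p <- pchisq(chi2, df, lower.tail = FALSE)
  sf <- survival::survfit(
    survival::Surv(survival@time, survival@event) ~ grp)
  sm <- summary(sf, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time)) else
    sub("^grp=", "", as.character(sm$strata))
  km <- data.frame(group = strata, time = sm$time, nRisk = sm$n.risk,
                   nEvent = sm$n.event, survival = sm$surv)
  new("SurvivalComparison", chi2 = chi2, df = df, pValue = p, kmCurves = km)
}

#' @importFrom stats p.adjust
NULL
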