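## Synthetic multi-omics cohorts with planted, survival-linked subtype
## structure: a shared cluster-structured latent signal mapped into each view
## through a fixed random nonlinear mixing (softplus), view-specific noise,
## sample-level missing views, exponential survival with cluster-dependent
## hazards under independent uniform censoring, and platform-shifted external
## cohorts sharing a subset of features.

#' Simulation configuration for planted-subtype multi-omics cohorts
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 300 samples, 2 planted clusters, three views with dimensions
#' emulating genes / promoter methylation / miRNAs, latent cluster separation
#' 8 (in latent-sd units), hazard ratio 3 between adjacent clusters, 10\%
#' missing views and a 50\% censoring target.
#'
#' @param nSamples cohort size (default 300).
#' @param nClusters planted cluster count K (default 2).
#' @param viewDims feature counts per view (default c(2000, 1500, 200)).
#' @param latentDim latent factor dimension (default 10).
#' @param clusterSeparation distance between cluster means in latent space,
#'   in units of the latent standard deviation (default 8).
#' @param sharedSignalFrac fraction of each view's features loading on the
#'   shared latent signal (default 0.2); the rest are pure noise.
#' @param noiseSd view-specific additive noise standard deviation
#'   (default 0.5).
#' @param missingViewRate probability that a sample drops any given view
#'   (default 0.1); at least one view is always retained.
#' @param hazardRatio multiplicative hazard between adjacent clusters
#'   (default 3).
#' @param baselineHazard hazard of cluster 1 (default 0.001 per day).
#' @param censoringRate target fraction of censored samples (default 0.5).
#' @param seed integer seed (default 1).
#' @export
simulationConfig <- function(nSamples = 300L, nClusters = 2L,
                             viewDims = c(2000L, 1500L, 200L),
                             latentDim = 10L, clusterSeparation = 8,
                             sharedSignalFrac = 0.2, noiseSd = 0.5,
                             missingViewRate = 0.1, hazardRatio = 3,
                             baselineHazard = 0.001, censoringRate = 0.5,
                             seed = 1L) {
  stopifnot(nSamples >= 2, nClusters >= 1, all(viewDims >= 1), latentDim >= 1,
            clusterSeparation >= 0, sharedSignalFrac >= 0,
            sharedSignalFrac <= 1, noiseSd >= 0, missingViewRate >= 0,
            missingViewRate < 1, hazardRatio > 0, baselineHazard > 0,
            censoringRate >= 0, censoringRate < 1)
  list(nSamples = as.integer(nSamples), nClusters = as.integer(nClusters),
       viewDims = as.integer(viewDims), latentDim = as.integer(latentDim),
       clusterSeparation = clusterSeparation,
       sharedSignalFrac = sharedSignalFrac, noiseSd = noiseSd,
       missingViewRate = missingViewRate, hazardRatio = hazardRatio,
       baselineHazard = baselineHazard, censoringRate = censoringRate,
       seed = as.integer(seed))
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# K cluster means, pairwise distance = sep, embedded in latentDim dims
.clusterMeans <- function(K, latentDim, sep) {
  mu <- matrix(0, K, latentDim)
  if (K > 1) {
    if (latentDim < K) stop("latentDim too small for ", K, " clusters")
    # scaled simplex corners sep/sqrt(2) * e_i: ||mu_i - mu_j|| = sep, i != j
    mu[cbind(seq_len(K), seq_len(K))] <- sep / sqrt(2)
  }
  mu
}

# max censoring-window length c so that P(censored) hits the target, for an
# exponential event-time mixture with hazards lambda_k in proportions pi_k
.calibrateCensoring <- function(lambda, pi_, target) {
  if (target == 0) return(Inf)
  pcens <- function(cmax)
    sum(pi_ * (1 - exp(-lambda * cmax)) / (lambda * cmax)) - target
  # pcens decreases from 1 (cmax -> 0) to 0 (cmax -> Inf)
  hi <- 1 / min(lambda)
  while (pcens(hi) > 0) hi <- hi * 2
  uniroot(pcens, c(1e-12, hi), tol = 1e-10)$root
}

#' Simulate a multi-omics cohort with planted survival-linked subtypes
#'
#' Each sample draws a cluster id uniformly and a latent factor
#' h ~ Normal(mu_cluster, I) with configured between-cluster separation.
#' View v observes A_v softplus(B_v h) + noise on its shared-signal features
#' (A_v, B_v fixed random mixing per seed) and pure noise elsewhere; the
#' softplus makes the view maps nonlinear, so a nonlinear shared
#' representation has an advantage over a linear one. Survival times are
#' exponential with hazard baselineHazard * hazardRatio^(cluster - 1);
#' censoring is independent uniform, with its window calibrated so the
#' expected censored fraction equals the target. Views are dropped
#' independently per sample at the configured rate, always retaining at
#' least one.
#'
#' @param cfg a [simulationConfig()].
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(cfg = simulationConfig()) {
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(cfg$seed)
  N <- cfg$nSamples; K <- cfg$nClusters; L <- cfg$latentDim
  ids <- sprintf("S%04d", seq_len(N))
  labels <- sample.int(K, N, replace = TRUE)
  mu <- .clusterMeans(K, L, cfg$clusterSeparation)
  H <- mu[labels, , drop = FALSE] + matrix(rnorm(N * L), N, L)
  rownames(H) <- ids

  mixing <- vector("list", length(cfg$viewDims))
  viewsRaw <- vector("list", length(cfg$viewDims))
  for (v in seq_along(cfg$viewDims)) {
    d <- cfg$viewDims[v]
    nShared <- round(cfg$sharedSignalFrac * d)
    B <- matrix(rnorm(L * L, sd = 1 / sqrt(L)), L, L)
    A <- matrix(rnorm(nShared * L, sd = 1 / sqrt(L)), nShared, L)
    mixing[[v]] <- list(A = A, B = B, nShared = nShared)
    vals <- matrix(rnorm(d * N, sd = max(cfg$noiseSd, 1e-12)), d, N)
    if (nShared > 0)
      vals[seq_len(nShared), ] <- vals[seq_len(nShared), ] +
        A %*% .softplus(B %*% t(H))
    dimnames(vals) <- list(sprintf("V%d_F%05d", v, seq_len(d)), ids)
    viewsRaw[[v]] <- vals
  }

  lambda <- cfg$baselineHazard * cfg$hazardRatio^(labels - 1)
  tEvent <- rexp(N, rate = lambda)
  lamK <- cfg$baselineHazard * cfg$hazardRatio^(seq_len(K) - 1)
  cmax <- .calibrateCensoring(lamK, rep(1 / K, K), cfg$censoringRate)
  tCens <- if (is.finite(cmax)) runif(N, 0, cmax) else rep(Inf, N)
  time <- pmin(tEvent, tCens)
  event <- as.integer(tEvent <= tCens)
  time <- pmax(time, 1e-8)

  drop <- matrix(runif(N * length(viewsRaw)) < cfg$missingViewRate, N)
  allDropped <- rowSums(!drop) == 0L
  if (any(allDropped))        # guarantee >= 1 retained view
    drop[cbind(which(allDropped),
               sample.int(ncol(drop), sum(allDropped), replace = TRUE))] <- FALSE

  viewList <- lapply(seq_along(viewsRaw), function(v) {
    keep <- !drop[, v]
    OmicsView(paste0("view", v), viewsRaw[[v]][, keep, drop = FALSE])
  })
  surv <- SurvivalTable(ids, time, event)
  dataset <- assembleDataset(viewList, surv)
  # assembleDataset orders the universe by appearance; reorder to ids
  new("SyntheticCohort", dataset = dataset,
      trueLabels = setNames(labels, ids)[sampleUniverse(dataset)],
      latent = H,
      generator = list(cfg = cfg, mixing = mixing, mu = mu))
}

#' Null cohort: no cluster structure, no survival difference
#'
#' [simulateCohort()] with cluster separation 0 and hazard ratio 1; used for
#' type-I-error calibration of the Cox filter and log-rank stages.
#'
#' @param cfg a [simulationConfig()]; its separation and hazard ratio are
#'   overridden.
#' @return a [SyntheticCohort-class].
#' @export
nullCohort <- function(cfg = simulationConfig()) {
  cfg$clusterSeparation <- 0
  cfg$hazardRatio <- 1
  simulateCohort(cfg)
}

#' Draw a platform-shifted external cohort from the same generative process
#'
#' Samples a fresh cohort from the generator stored on \code{cohort}, keeps
#' one view, restricts it to a random \code{overlapFrac} subset of features
#' (emulating partial feature overlap between platforms), and applies a
#' per-feature strictly monotone warp \eqn{x \to a x + b + c\,\tanh(x)} with
#' \eqn{a > 0} and \eqn{|c| \le} \code{warpStrength} * a (monotone by
#' construction; violating parameters are rejected), plus fresh measurement
#' noise.
#'
#' @param cohort a [SyntheticCohort-class] from [simulateCohort()].
#' @param viewIndex which view the external platform measures (default 1).
#' @param nExternal external cohort size (default: same as training).
#' @param overlapFrac fraction of the view's features present on the external
#'   platform, in (0, 1\].
#' @param shiftScale scale of the per-feature affine shift (default 0.5).
#' @param warpStrength bound on the nonlinear warp relative to the linear
#'   coefficient, in \[0, 1) (default 0.5).
#' @param newNoiseSd fresh measurement noise sd (default: training noiseSd).
#' @param seed integer seed for the external draw.
#' @return list: \code{view} (external [OmicsView-class]), \code{labels}
#'   (planted cluster ids), \code{survival} (external [SurvivalTable-class]).
#' @export
simulatePlatformShift <- function(cohort, viewIndex = 1L, nExternal = NULL,
                                  overlapFrac = 0.65, shiftScale = 0.5,
                                  warpStrength = 0.5, newNoiseSd = NULL,
                                  seed = 1L) {
  if (overlapFrac <= 0 || overlapFrac > 1)
    stop("overlapFrac must be in (0, 1]")
  if (warpStrength < 0 || warpStrength >= 1)
    stop("warpStrength must be in [0, 1) to preserve strict monotonicity")
  gen <- cohort@generator
  cfg <- gen$cfg
  if (is.null(nExternal)) nExternal <- cfg$nSamples
  if (is.null(newNoiseSd)) newNoiseSd <- cfg$noiseSd
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)

  N <- nExternal; K <- cfg$nClusters; L <- cfg$latentDim
  ids <- sprintf("X%04d", seq_len(N))
  labels <- sample.int(K, N, replace = TRUE)
  H <- gen$mu[labels, , drop = FALSE] + matrix(rnorm(N * L), N, L)
  mix <- gen$mixing[[viewIndex]]
  d <- cfg$viewDims[viewIndex]
  vals <- matrix(rnorm(d * N, sd = max(newNoiseSd, 1e-12)), d, N)
  if (mix$nShared > 0)
    vals[seq_len(mix$nShared), ] <- vals[seq_len(mix$nShared), ] +
      mix$A %*% .softplus(mix$B %*% t(H))
  dimnames(vals) <- list(sprintf("V%d_F%05d", viewIndex, seq_len(d)), ids)

  keep <- sort(sample.int(d, max(1L, round(overlapFrac * d))))
  vals <- vals[keep, , drop = FALSE]
  a <- exp(rnorm(length(keep), sd = shiftScale))
  b <- rnorm(length(keep), sd = shiftScale)
  cc <- warpStrength * a * runif(length(keep), -1, 1)
  vals <- a * vals + b + cc * tanh(vals)

  lambda <- cfg$baselineHazard * cfg$hazardRatio^(labels - 1)
  tEvent <- rexp(N, rate = lambda)
  lamK <- cfg$baselineHazard * cfg$hazardRatio^(seq_len(K) - 1)
  cmax <- .calibrateCensoring(lamK, rep(1 / K, K), cfg$censoringRate)
  tCens <- if (is.finite(cmax)) runif(N, 0, cmax) else rep(Inf, N)
  list(view = OmicsView(paste0("view", viewIndex, "_external"), vals),
       labels = setNames(labels, ids),
       survival = SurvivalTable(ids, pmax(pmin(tEvent, tCens), 1e-8),
                                as.integer(tEvent <= tCens)))
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' One TSV per view, a survival TSV and a truth table (sample_id, cluster).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (i in seq_along(cohort@dataset@views)) {
    v <- cohort@dataset@views[[i]]
    paths[[v@name]] <- file.path(dir, paste0(v@name, ".tsv"))
    writeOmicsView(v, paths[[v@name]])
  }
  paths$survival <- file.path(dir, "survival.tsv")
  writeSurvivalTable(cohort@dataset@survival, paths$survival)
  paths$truth <- file.path(dir, "truth.tsv")
  write.table(data.frame(sample_id = names(cohort@trueLabels),
                         cluster = cohort@trueLabels),
              paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
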