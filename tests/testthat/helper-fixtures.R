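# Shared fixtures and independent oracles used across test files.

# small OmicsView built from a matrix, with generated ids
makeView <- function(vals, name = "v", features = NULL, samples = NULL) {
  if (is.null(features)) features <- paste0("f", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(vals)))
  dimnames(vals) <- list(features, samples)
  OmicsView(name, vals)
}

randomView <- function(d, n, name = "v", seed = 1) {
  set.seed(seed)
  makeView(matrix(rnorm(d * n), d, n), name)
}

# simple survival table with exponential times, optional binary group effect
makeSurvival <- function(n, seed = 1, hr = 1, group = NULL, censor = 0.3) {
  set.seed(seed)
  if (is.null(group)) group <- rep(0L, n)
  tEvent <- rexp(n, rate = 0.01 * hr^group)
  tCens <- if (censor > 0) rexp(n, rate = 0.01 * censor / (1 - censor)) else
    rep(Inf, n)
  SurvivalTable(paste0("s", seq_len(n)), pmin(tEvent, tCens) + 1e-9,
                as.integer(tEvent <= tCens))
}

# dense-solve GCCA oracle: independent of the package's SVD route
denseGccaOracle <- function(outputs, r, rho = 1e-6, weights = NULL) {
  V <- length(outputs)
  if (is.null(weights)) weights <- rep(1, V)
  N <- ncol(outputs[[1]])
  Ys <- lapply(outputs, function(Y) Y - rowMeans(Y))
  M <- matrix(0, N, N)
  for (v in seq_len(V)) {
    Y <- Ys[[v]]
    M <- M + weights[v] *
      (t(Y) %*% solve(Y %*% t(Y) + rho * diag(nrow(Y))) %*% Y)
  }
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  G <- t(es$vectors[, seq_len(r), drop = FALSE])
  obj <- 0
  for (v in seq_len(V)) {
    Y <- Ys[[v]]
    U <- solve(Y %*% t(Y) + rho * diag(nrow(Y))) %*% Y %*% t(G)
    obj <- obj + weights[v] * sum((G - t(U) %*% Y)^2)
  }
  list(G = G, objective = obj, eigenvalues = es$values)
}

# hand-tabulated k-group log-rank chi-square (O - E with hypergeometric
# variance), the textbook construction, independent of survival::survdiff
handLogrank <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  tt <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  Vmat <- matrix(0, k, k)
  for (t0 in tt) {
    atRisk <- time >= t0
    n <- sum(atRisk)
    d <- sum(event == 1 & time == t0)
    for (i in seq_len(k)) {
      ni <- sum(atRisk & group == groups[i])
      O[i] <- O[i] + sum(event == 1 & time == t0 & group == groups[i])
      E[i] <- E[i] + d * ni / n
      for (j in seq_len(k)) {
        nj <- sum(atRisk & group == groups[j])
        delta <- as.numeric(i == j)
        if (n > 1)
          Vmat[i, j] <- Vmat[i, j] +
            d * (ni / n) * (delta - nj / n) * (n - d) / (n - 1)
      }
    }
  }
  idx <- seq_len(k - 1)
  z <- (O - E)[idx]
  chi2 <- as.numeric(t(z) %*% solve(Vmat[idx, idx, drop = FALSE]) %*% z)
  list(chi2 = chi2, O = O, E = E)
}

adjRandIndex <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny planted two-cluster cohort for fast pipeline-level tests
smallPlantedCohort <- function(seed = 1, n = 150) {
  simulateCohort(simulationConfig(
    nSamples = n, viewDims = c(150L, 100L, 60L), missingViewRate = 0.1,
    seed = seed))
}
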