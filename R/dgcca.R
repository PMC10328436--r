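## Deep generalized CCA: per-view two-layer networks trained full-batch under
## the GCCA objective  min_{G,U} sum_v w_v ||(G - U_v^T f_v(X_v)) D_v||_F^2
## s.t. G G^T = I, with covariance regularization rho and missing-view masks.

#' Per-view network configuration
#'
#' @param hiddenUnits hidden layer width (default 500).
#' @param outputUnits output embedding layer width (default 100).
#' @param activation hidden activation: "relu", "tanh" or "identity". The
#'   output layer is linear so the GCCA loss sees an unconstrained range.
#' @param l1,l2 L1/L2 penalty constants on weight matrices (not biases);
#'   defaults 0.001 and 0.0001.
#' @return list of class settings consumed by [trainDgcca()].
#' @export
viewNetworkConfig <- function(hiddenUnits = 500L, outputUnits = 100L,
                              activation = c("relu", "tanh", "identity"),
                              l1 = 0.001, l2 = 0.0001) {
  activation <- match.arg(activation)
  stopifnot(hiddenUnits >= 1, outputUnits >= 1, l1 >= 0, l2 >= 0)
  list(hiddenUnits = as.integer(hiddenUnits),
       outputUnits = as.integer(outputUnits),
       activation = activation, l1 = l1, l2 = l2)
}

#' GCCA / training configuration
#'
#' @param embeddingDim r, the dimension of the shared representation
#'   (default 100).
#' @param viewRank rank of the truncated factorization applied to each view's
#'   (centered, masked) output matrix before solving (default 100; a no-op
#'   whenever it is at least the matrix rank).
#' @param covReg ridge added to each view's output covariance (default 1e-6).
#' @param viewWeights nonnegative per-view weights; default all 1 (equal).
#' @param epochs full-batch gradient descent epochs (default 20).
#' @param learningRate step size (default 0.001; see the methods vignette for
#'   why a conservative full-batch rate is used at r close to rank(Y_v)).
#' @param seed integer seed controlling weight initialization.
#' @export
gccaConfig <- function(embeddingDim = 100L, viewRank = 100L, covReg = 1e-6,
                       viewWeights = NULL, epochs = 20L, learningRate = 0.001,
                       seed = 1L) {
  stopifnot(embeddingDim >= 1, viewRank >= embeddingDim, covReg >= 0,
            epochs >= 1, learningRate > 0)
  list(embeddingDim = as.integer(embeddingDim),
       viewRank = as.integer(viewRank), covReg = covReg,
       viewWeights = viewWeights, epochs = as.integer(epochs),
       learningRate = learningRate, seed = as.integer(seed))
}

.activate <- function(z, activation) {
  switch(activation, relu = pmax(z, 0), tanh = tanh(z), identity = z)
}

.activateGrad <- function(z, activation) {
  switch(activation, relu = (z > 0) * 1, tanh = 1 - tanh(z)^2,
         identity = array(1, dim(z)))
}

#' Initialize a two-layer view network
#'
#' He-style scaled Gaussian weights, zero biases; deterministic given the
#' supplied RNG state (call within a seeded context).
#'
#' @param inputDim number of input features d_v.
#' @param cfg a [viewNetworkConfig()].
#' @return network parameter list (W1, b1, W2, b2, activation).
#' @export
initViewNetwork <- function(inputDim, cfg) {
  h <- cfg$hiddenUnits; o <- cfg$outputUnits
  list(W1 = matrix(rnorm(h * inputDim, sd = sqrt(2 / inputDim)), h, inputDim),
       b1 = numeric(h),
       W2 = matrix(rnorm(o * h, sd = sqrt(2 / h)), o, h),
       b2 = numeric(o),
       activation = cfg$activation)
}

#' Forward pass of a view network
#'
#' hidden = activation(W1 X + b1); output = W2 hidden + b2 (linear output).
#'
#' @param network parameter list from [initViewNetwork()].
#' @param X d_v x N input matrix.
#' @return output_units x N output matrix.
#' @export
forwardView <- function(network, X) {
  if (nrow(network$W1) == 0L || ncol(network$W1) != nrow(X))
    stop(sprintf("network expects %d input features, got %d",
                 ncol(network$W1), nrow(X)))
  Z1 <- network$W1 %*% X + network$b1
  H <- .activate(Z1, network$activation)
  network$W2 %*% H + network$b2
}

# Backprop dL/d(output) through the network; returns parameter gradients.
.backwardView <- function(network, X, dOut, l1 = 0, l2 = 0) {
  Z1 <- network$W1 %*% X + network$b1
  H <- .activate(Z1, network$activation)
  dW2 <- dOut %*% t(H) + l1 * sign(network$W2) + 2 * l2 * network$W2
  db2 <- rowSums(dOut)
  dH <- crossprod(network$W2, dOut)
  dZ1 <- dH * .activateGrad(Z1, network$activation)
  dW1 <- dZ1 %*% t(X) + l1 * sign(network$W1) + 2 * l2 * network$W1
  db1 <- rowSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# Center each row over present samples, zero absent columns, and return the
# truncated SVD pieces needed by the solver.
.prepareView <- function(Y, present, viewRank, covReg) {
  Yc <- Y
  if (any(present)) {
    mu <- rowMeans(Y[, present, drop = FALSE])
    Yc <- Y - mu
  }
  Yc[, !present] <- 0
  sv <- svd(Yc)
  tol <- max(dim(Yc)) * max(sv$d, 0) * .Machine$double.eps
  keep <- which(sv$d > tol)
  keep <- head(keep, viewRank)
  list(Yc = Yc,
       u = sv$u[, keep, drop = FALSE],
       d = sv$d[keep],
       v = sv$v[, keep, drop = FALSE])
}

# deterministic sign: first entry larger (in modulus) than tol is positive
.fixSigns <- function(V, tol = 1e-9) {
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > tol)
    if (length(nz) && V[nz[1], j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Solve the (masked, regularized) generalized CCA problem
#'
#' Given per-view network outputs Y_v (output_units x N, columns aligned to a
#' common sample universe) and a presence mask, centers each view's rows over
#' its present samples, zeroes absent columns, and solves
#' \deqn{\min \sum_v w_v \|(G - U_v^T Y_v) D_v\|_F^2,\quad G G^T = I,}
#' where D_v restricts to present samples. With the optimal U substituted the
#' objective equals \eqn{tr(G (D - M) G^T)} with
#' \eqn{M = \sum_v w_v Y_v^T (Y_v Y_v^T + \rho I)^{-1} Y_v} (computed through
#' a rank-\code{viewRank} truncated SVD of each Y_v) and D the diagonal
#' per-sample availability \eqn{\sum_v w_v 1[present]}; the rows of G are the
#' bottom-r eigenvectors of D - M (equivalently, with complete views, the
#' classical top-r eigenvectors of M), with a deterministic
#' first-nonzero-positive sign convention, and
#' \eqn{U_v = (Y_v Y_v^T + \rho I)^{-1} Y_v G^T}. The \code{eigenvalues} slot
#' reports the per-direction sharedness \eqn{\sum_v w_v - \mu_j}, which is
#' exactly the eigenvalue of M when no views are missing.
#'
#' @param outputs list of V numeric matrices, each output_units x N.
#' @param presence N x V logical matrix (default: all present).
#' @param cfg a [gccaConfig()].
#' @return a [GccaSolution-class].
#' @export
gccaSolve <- function(outputs, presence = NULL, cfg = gccaConfig()) {
  V <- length(outputs)
  if (V < 2L) stop("GCCA requires at least 2 views")
  N <- ncol(outputs[[1]])
  stopifnot(all(vapply(outputs, ncol, 1L) == N))
  if (is.null(presence)) presence <- matrix(TRUE, N, V)
  r <- cfg$embeddingDim
  if (r > N) stop("embedding dimension r (", r, ") exceeds sample count ", N)
  w <- cfg$viewWeights
  if (is.null(w)) w <- rep(1, V)
  stopifnot(length(w) == V, all(w >= 0))
  rho <- cfg$covReg

  prep <- vector("list", V)
  M <- matrix(0, N, N)
  avail <- numeric(N)
  for (v in seq_len(V)) {
    prep[[v]] <- .prepareView(outputs[[v]], presence[, v], cfg$viewRank, rho)
    d <- prep[[v]]$d
    # P_v = V diag(d^2/(d^2+rho)) V^T via the truncated SVD
    if (length(d))
      M <- M + w[v] * (prep[[v]]$v %*% (d^2 / (d^2 + rho) * t(prep[[v]]$v)))
    avail <- avail + w[v] * presence[, v]
  }
  # The objective with U at its optimum is tr(G (D - M) G^T) with D the
  # diagonal per-sample availability sum(w_v * present). With complete views
  # D = sum(w) I and the minimizer is the classical top-r eigenvectors of M;
  # with missing views the objective-consistent minimizer is the bottom-r
  # eigenspace of D - M, which does not shrink incomplete samples' rows.
  A <- diag(avail, N) - (M + t(M)) / 2
  es <- eigen(A, symmetric = TRUE)
  sel <- seq.int(N, by = -1L, length.out = r)   # smallest eigenvalues
  G <- t(.fixSigns(es$vectors[, sel, drop = FALSE]))
  colnames(G) <- colnames(outputs[[1]])
  sharedness <- sum(w) - es$values[sel]

  U <- vector("list", V)
  resid <- numeric(V)
  for (v in seq_len(V)) {
    p <- prep[[v]]
    # C^{-1} Y = u diag(d/(d^2+rho)) v^T on the retained rank
    U[[v]] <- p$u %*% ((p$d / (p$d^2 + rho)) * crossprod(p$v, t(G)))
    R <- G - crossprod(U[[v]], p$Yc)
    resid[v] <- sum(R[, presence[, v], drop = FALSE]^2)
  }
  new("GccaSolution", G = G, U = U, objective = sum(w * resid),
      perViewResiduals = resid,
      eigenvalues = sharedness)
}

#' GCCA objective and its gradient with respect to the view outputs
#'
#' Solves the GCCA problem at the supplied outputs and returns the objective
#' together with its gradient in each view's output matrix. By Danskin's
#' theorem the gradient at the optimal (G, U) is
#' \eqn{2 w_v (U_v U_v^T Y_v - U_v G)} on present columns, pushed through the
#' per-view centering operator (centering is part of the solve); absent
#' samples' columns are zero.
#'
#' @inheritParams gccaSolve
#' @return list with \code{objective}, \code{grads} (list of V matrices) and
#'   the full \code{solution}.
#' @export
gccaLossAndGrads <- function(outputs, presence = NULL, cfg = gccaConfig()) {
  V <- length(outputs)
  N <- ncol(outputs[[1]])
  if (is.null(presence)) presence <- matrix(TRUE, N, V)
  sol <- gccaSolve(outputs, presence, cfg)
  w <- cfg$viewWeights
  if (is.null(w)) w <- rep(1, V)
  grads <- vector("list", V)
  for (v in seq_len(V)) {
    pres <- presence[, v]
    mu <- if (any(pres)) rowMeans(outputs[[v]][, pres, drop = FALSE]) else 0
    Yc <- outputs[[v]] - mu
    Yc[, !pres] <- 0
    Uv <- sol@U[[v]]
    Gv <- 2 * w[v] * (Uv %*% (crossprod(Uv, Yc) - sol@G))
    Gv[, !pres] <- 0
    # chain rule through row-centering over present samples
    if (any(pres))
      Gv[, pres] <- Gv[, pres, drop = FALSE] -
        rowMeans(Gv[, pres, drop = FALSE])
    grads[[v]] <- Gv
  }
  list(objective = sol@objective, grads = grads, solution = sol)
}

# Build universe-aligned output matrices (absent columns zero) for a dataset.
.forwardDataset <- function(networks, dataset) {
  uni <- sampleUniverse(dataset)
  lapply(seq_along(dataset@views), function(v) {
    vw <- dataset@views[[v]]
    out <- matrix(0, nrow(networks[[v]]$W2), length(uni),
                  dimnames = list(NULL, uni))
    fwd <- forwardView(networks[[v]], vw@values)
    out[, colnames(vw@values)] <- fwd
    out
  })
}

#' Train the deep GCCA model by full-batch gradient descent
#'
#' Each epoch forwards every view through its two-layer network, solves the
#' GCCA problem on the outputs, backpropagates the objective (plus L1/L2
#' weight penalties) through the networks, and takes one full-batch gradient
#' step. Defaults follow the reference configuration: 500 hidden / 100 output
#' units, ReLU hidden activation, L1 0.001, L2 0.0001, covariance ridge 1e-6,
#' r = 100, equal view weights, 20 epochs.
#'
#' @param dataset a [MultiOmicsDataset-class].
#' @param netConfigs list of per-view [viewNetworkConfig()]s (recycled from a
#'   single config if needed).
#' @param cfg a [gccaConfig()]; \code{cfg$seed} controls initialization.
#' @return a [TrainedDgcca-class].
#' @export
trainDgcca <- function(dataset, netConfigs = viewNetworkConfig(),
                       cfg = gccaConfig()) {
  V <- length(dataset@views)
  if (!is.null(netConfigs$hiddenUnits)) netConfigs <- list(netConfigs)
  if (length(netConfigs) == 1L) netConfigs <- rep(netConfigs, V)
  stopifnot(length(netConfigs) == V)
  if (any(vapply(dataset@views, function(v) ncol(v@values), 1L) == 0L))
    stop("every view must contain at least one sample")
  r <- cfg$embeddingDim
  N <- nrow(dataset@presence)
  if (r > N) stop("embedding dimension exceeds number of samples")

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(cfg$seed)
  networks <- lapply(seq_len(V), function(v)
    initViewNetwork(nrow(dataset@views[[v]]@values), netConfigs[[v]]))

  lr <- cfg$learningRate
  loss <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    outputs <- .forwardDataset(networks, dataset)
    lg <- gccaLossAndGrads(outputs, dataset@presence, cfg)
    pen <- sum(vapply(seq_len(V), function(v) {
      nc <- netConfigs[[v]]
      nc$l1 * (sum(abs(networks[[v]]$W1)) + sum(abs(networks[[v]]$W2))) +
        nc$l2 * (sum(networks[[v]]$W1^2) + sum(networks[[v]]$W2^2))
    }, numeric(1)))
    loss[epoch] <- lg$objective + pen
    if (!is.finite(loss[epoch]))
      stop("non-finite loss at epoch ", epoch,
           "; reduce learningRate (currently ", lr, ")")
    for (v in seq_len(V)) {
      vw <- dataset@views[[v]]
      dOut <- lg$grads[[v]][, colnames(vw@values), drop = FALSE]
      g <- .backwardView(networks[[v]], vw@values, dOut,
                         netConfigs[[v]]$l1, netConfigs[[v]]$l2)
      networks[[v]]$W1 <- networks[[v]]$W1 - lr * g$W1
      networks[[v]]$b1 <- networks[[v]]$b1 - lr * g$b1
      networks[[v]]$W2 <- networks[[v]]$W2 - lr * g$W2
      networks[[v]]$b2 <- networks[[v]]$b2 - lr * g$b2
    }
  }
  outputs <- .forwardDataset(networks, dataset)
  final <- gccaSolve(outputs, dataset@presence, cfg)
  new("TrainedDgcca", networks = networks, netConfigs = netConfigs,
      gccaConfig = cfg, finalSolution = final, lossHistory = loss)
}

#' Embed every sample of a dataset into the shared representation
#'
#' Forwards the dataset through the trained networks and re-solves the masked
#' GCCA problem over the full sample universe; every sample (including those
#' with missing views) receives one r-dimensional row.
#'
#' @param model a [TrainedDgcca-class].
#' @param dataset a [MultiOmicsDataset-class] whose views match the model's
#'   input dimensions (same features, same order).
#' @return N x r numeric matrix with sample ids as rownames.
#' @export
embedSamples <- function(model, dataset) {
  for (v in seq_along(dataset@views)) {
    d_model <- ncol(model@networks[[v]]$W1)
    d_data <- nrow(dataset@views[[v]]@values)
    if (d_model != d_data)
      stop(sprintf("view %d: model expects %d features, dataset has %d",
                   v, d_model, d_data))
  }
  outputs <- .forwardDataset(model@networks, dataset)
  sol <- gccaSolve(outputs, dataset@presence, model@gccaConfig)
  emb <- t(sol@G)
  rownames(emb) <- sampleUniverse(dataset)
  colnames(emb) <- paste0("E", seq_len(ncol(emb)))
  emb
}

# Save/restore .Random.seed so seeded internals do not disturb the caller.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
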