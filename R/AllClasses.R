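#' @import methods
#' @importFrom stats quantile sd var median pchisq rnorm runif rexp rbinom
#'   setNames aggregate kmeans dist coef predict uniroot
#' @importFrom utils read.delim write.table head modifyList
NULL

#' One -omics modality: a features x samples matrix with a missing-entry mask
#'
#' An \code{OmicsView} holds one -omics data type (gene expression, promoter
#' methylation beta-values, miRNA abundance, ...) as a real-valued matrix with
#' features in rows and samples in columns, together with a logical mask that
#' is \code{TRUE} wherever the entry is missing. Feature and sample identifiers
#' are carried as the dimnames of the matrix and must be unique.
#'
#' @slot name single character label for the modality.
#' @slot values numeric matrix, features x samples, with unique dimnames.
#' @slot missingMask logical matrix of the same shape; \code{TRUE} = missing.
#'   The mask is \code{TRUE} wherever \code{values} is non-finite.
#'
#' @seealso [readOmicsView()], [filterMissingness()], [knnImpute()]
#' @export
setClass("OmicsView",
  representation(name = "character", values = "matrix", missingMask = "matrix"))

setValidity("OmicsView", function(object) {
  v <- object@values; m <- object@missingMask
  if (length(object@name) != 1L) return("'name' must be a single label")
  if (!is.numeric(v)) return("'values' must be numeric")
  if (!is.logical(m)) return("'missingMask' must be logical")
  if (!identical(dim(v), dim(m))) return("values and missingMask shapes differ")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry feature (row) and sample (column) names")
  if (anyDuplicated(rownames(v))) return("duplicated feature ids")
  if (anyDuplicated(colnames(v))) return("duplicated sample ids")
  if (any(!is.finite(v) & !m))
    return("non-finite values present that are not flagged in missingMask")
  TRUE
})

#' Right-censored survival records for a sample universe
#'
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot time positive follow-up times.
#' @slot event integer 0/1 event indicator (1 = event observed, 0 = censored).
#' @slot timeUnit unit label ("days", "months", ...); recorded, never converted.
#' @export
setClass("SurvivalTable",
  representation(sampleIds = "character", time = "numeric",
                 event = "integer", timeUnit = "character"))

setValidity("SurvivalTable", function(object) {
  n <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds)) return("duplicated sample ids")
  if (length(object@time) != n || length(object@event) != n)
    return("time/event length must match sampleIds")
  if (any(!is.finite(object@time)) || any(object@time <= 0))
    return("all survival times must be positive and finite")
  if (!all(object@event %in% c(0L, 1L))) return("event must be 0 or 1")
  TRUE
})

#' Aligned multi-omics dataset over a common sample universe
#'
#' Collects V views over the union of their sample sets. A sample may be
#' absent from a view ("missing view"); the presence matrix records, per
#' sample and view, whether that sample has data in that view. Samples with
#' missing views are kept, not dropped: downstream computations exclude the
#' absent columns via the presence mask.
#'
#' @slot views list of [OmicsView-class] objects.
#' @slot presence logical matrix, samples (universe) x views.
#' @slot survival a [SurvivalTable-class] covering the whole universe.
#' @export
setClass("MultiOmicsDataset",
  representation(views = "list", presence = "matrix", survival = "SurvivalTable"))

setValidity("MultiOmicsDataset", function(object) {
  if (length(object@views) < 1L) return("at least one view required")
  if (!all(vapply(object@views, is, logical(1), "OmicsView")))
    return("views must all be OmicsView objects")
  uni <- rownames(object@presence)
  if (ncol(object@presence) != length(object@views))
    return("presence must have one column per view")
  if (any(rowSums(object@presence) < 1L))
    return("every sample must be present in at least one view")
  for (i in seq_along(object@views)) {
    sv <- colnames(object@views[[i]]@values)
    if (!setequal(sv, uni[object@presence[, i]]))
      return(sprintf("presence column %d disagrees with view sample set", i))
  }
  if (!setequal(object@survival@sampleIds, uni))
    return("survival table must cover exactly the sample universe")
  TRUE
})

#' Solution of the (masked) generalized CCA eigenproblem
#'
#' @slot G shared representation, r x N, orthonormal rows (one column per
#'   sample in the universe).
#' @slot U list of per-view projection matrices (output_units x r).
#' @slot objective total reconstruction objective
#'   \eqn{\sum_v w_v \| (G - U_v^T Y_v) D_v \|_F^2}.
#' @slot perViewResiduals per-view residual norms (the summands above).
#' @slot eigenvalues the top-r eigenvalues of the summed projector matrix M.
#' @export
setClass("GccaSolution",
  representation(G = "matrix", U = "list", objective = "numeric",
                 perViewResiduals = "numeric", eigenvalues = "numeric"))

setValidity("GccaSolution", function(object) {
  G <- object@G
  if (max(abs(tcrossprod(G) - diag(nrow(G)))) > 1e-6)
    return("rows of G must be orthonormal (GG^T = I)")
  if (length(object@perViewResiduals) != length(object@U))
    return("one residual per view required")
  TRUE
})

#' A trained deep-GCCA model: per-view networks plus the final solution
#'
#' @slot networks list of per-view two-layer networks (weights and biases).
#' @slot netConfigs list of per-view network configurations.
#' @slot gccaConfig the GCCA configuration used for training.
#' @slot finalSolution the [GccaSolution-class] at the final epoch.
#' @slot lossHistory penalized objective per epoch (length = epochs).
#' @export
setClass("TrainedDgcca",
  representation(networks = "list", netConfigs = "list", gccaConfig = "list",
                 finalSolution = "GccaSolution", lossHistory = "numeric"))

#' k-means clustering result with internal validation indices
#'
#' @slot k number of clusters.
#' @slot centroids k x p centroid matrix.
#' @slot labels integer cluster label in 1..k per sample.
#' @slot inertia best (minimum over restarts) within-cluster sum of squares.
#' @slot avgSilhouette mean silhouette width (NA when undefined).
#' @slot chScore Calinski-Harabasz score.
#' @slot perSampleSilhouette silhouette width per sample.
#' @export
setClass("ClusterModel",
  representation(k = "integer", centroids = "matrix", labels = "integer",
                 inertia = "numeric", avgSilhouette = "numeric",
                 chScore = "numeric", perSampleSilhouette = "numeric"))

setValidity("ClusterModel", function(object) {
  if (object@k < 2L && length(object@labels) > 1L) return("k must be >= 2")
  if (!all(seq_len(object@k) %in% object@labels)) return("empty cluster")
  TRUE
})

#' Log-rank comparison of survival between groups, with Kaplan-Meier curves
#'
#' @slot chi2 log-rank chi-square statistic.
#' @slot df degrees of freedom (number of groups - 1).
#' @slot pValue upper-tail chi-square p-value.
#' @slot kmCurves data.frame of product-limit curves: group, time, nRisk,
#'   nEvent, survival.
#' @export
setClass("SurvivalComparison",
  representation(chi2 = "numeric", df = "integer", pValue = "numeric",
                 kmCurves = "data.frame"))

#' Per-feature scaling model: training medians and post-centering moments
#'
#' Median scaling centers every feature at its training median. The mean and
#' standard deviation of the median-centered training matrix are stored so an
#' external cohort can later be standardized to the training moments.
#'
#' @slot featureIds feature identifiers, training order.
#' @slot center per-feature training median.
#' @slot method "center" (value - median, the default) or "divide"
#'   (value / median).
#' @slot mean per-feature mean of the median-scaled training values.
#' @slot sd per-feature standard deviation of the median-scaled values.
#' @slot constant logical; TRUE for zero-spread features (sd == 0).
#' @export
setClass("ScalerModel",
  representation(featureIds = "character", center = "numeric",
                 method = "character", mean = "numeric",
                 sd = "numeric", constant = "logical"),
  prototype(method = "center"))

#' Equal-frequency discretization model (training quantile edges)
#'
#' @slot nBins requested number of bins B.
#' @slot edges named list; per feature, the ascending interior cut points
#'   (at most B-1; duplicate quantiles are merged, yielding fewer effective
#'   bins for heavily tied features).
#' @export
setClass("BinningModel",
  representation(nBins = "integer", edges = "list"))

#' Result of random-forest recursive feature elimination
#'
#' @slot ranking feature ids ranked by decreasing importance (full-data fit).
#' @slot cvCurve data.frame: size, meanAccuracy, sdAccuracy over repeated CV.
#' @slot chosenN selected feature count (one-standard-error elbow rule).
#' @slot chosenFeatures the top chosenN features of the ranking.
#' @export
setClass("FeatureSelection",
  representation(ranking = "character", cvCurve = "data.frame",
                 chosenN = "integer", chosenFeatures = "character"))

#' Trained per-omics subtype classifier with its preprocessing artifacts
#'
#' Bundles everything needed to call subtypes on new data measured on another
#' platform: the selected features, the boosted-tree ensemble (serialized),
#' the tuned hyperparameters, cross-validation metrics, and the scaler and
#' binning models that must be applied to external data before prediction.
#'
#' @slot features selected feature ids (model input order).
#' @slot boosterRaw serialized xgboost model (raw vector).
#' @slot params tuned hyperparameter list.
#' @slot classLevels subtype labels in model class order.
#' @slot cvAccuracy mean cross-validated accuracy.
#' @slot cvAuc mean cross-validated AUC (one-vs-rest macro for k > 2).
#' @slot scaler the [ScalerModel-class] fitted on training data.
#' @slot bins the [BinningModel-class] fitted on scaled training data.
#' @export
setClass("SubtypeClassifier",
  representation(features = "character", boosterRaw = "raw", params = "list",
                 classLevels = "character", cvAccuracy = "numeric",
                 cvAuc = "numeric", scaler = "ScalerModel",
                 bins = "BinningModel"))

#' Synthetic multi-omics cohort with planted subtype structure
#'
#' @slot dataset the generated [MultiOmicsDataset-class].
#' @slot trueLabels planted cluster id per sample (named integer).
#' @slot latent the generating latent factors (samples x latent_dim).
#' @slot generator internal generator state (mixing matrices, config) used to
#'   draw platform-shifted external cohorts from the same process.
#' @export
setClass("SyntheticCohort",
  representation(dataset = "MultiOmicsDataset", trueLabels = "integer",
                 latent = "matrix", generator = "list"))

setValidity("SyntheticCohort", function(object) {
  uni <- rownames(object@dataset@presence)
  if (!identical(names(object@trueLabels), uni))
    return("trueLabels must be named by the sample universe, in order")
  TRUE
})
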