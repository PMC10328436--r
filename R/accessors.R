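#' @describeIn OmicsView-class construct an OmicsView from a matrix; the
#'   missing mask is inferred from non-finite entries unless given.
#' @param name modality label.
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param missingMask optional logical matrix; defaults to \code{!is.finite}.
#' @export
OmicsView <- function(name, values, missingMask = NULL) {
  if (is.null(missingMask)) missingMask <- !is.finite(values)
  dimnames(missingMask) <- dimnames(values)
  new("OmicsView", name = name, values = values, missingMask = missingMask)
}

#' Construct a SurvivalTable
#' @param sampleIds unique sample identifiers.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param timeUnit unit label, recorded but never converted.
#' @export
SurvivalTable <- function(sampleIds, time, event, timeUnit = "days") {
  new("SurvivalTable", sampleIds = as.character(sampleIds),
      time = as.numeric(time), event = as.integer(event), timeUnit = timeUnit)
}

#' @rdname OmicsView-class
#' @param object,x an OmicsView.
#' @export
setGeneric("viewName", function(x) standardGeneric("viewName"))
#' @rdname OmicsView-class
#' @export
setMethod("viewName", "OmicsView", function(x) x@name)

#' @rdname OmicsView-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname OmicsView-class
#' @export
setMethod("featureIds", "OmicsView", function(x) rownames(x@values))

#' @rdname OmicsView-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname OmicsView-class
#' @export
setMethod("sampleIds", "OmicsView", function(x) colnames(x@values))
#' @rdname SurvivalTable-class
#' @param x a SurvivalTable.
#' @export
setMethod("sampleIds", "SurvivalTable", function(x) x@sampleIds)

#' @rdname OmicsView-class
#' @export
setGeneric("viewValues", function(x) standardGeneric("viewValues"))
#' @rdname OmicsView-class
#' @export
setMethod("viewValues", "OmicsView", function(x) x@values)

#' @rdname OmicsView-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname OmicsView-class
#' @export
setMethod("missingMask", "OmicsView", function(x) x@missingMask)

#' @rdname MultiOmicsDataset-class
#' @param x a MultiOmicsDataset.
#' @export
setGeneric("views", function(x) standardGeneric("views"))
#' @rdname MultiOmicsDataset-class
#' @export
setMethod("views", "MultiOmicsDataset", function(x) x@views)

#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("sampleUniverse", function(x) standardGeneric("sampleUniverse"))
#' @rdname MultiOmicsDataset-class
#' @export
setMethod("sampleUniverse", "MultiOmicsDataset",
          function(x) rownames(x@presence))

#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("viewPresence", function(x) standardGeneric("viewPresence"))
#' @rdname MultiOmicsDataset-class
#' @export
setMethod("viewPresence", "MultiOmicsDataset", function(x) x@presence)

#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("survivalTable", function(x) standardGeneric("survivalTable"))
#' @rdname MultiOmicsDataset-class
#' @export
setMethod("survivalTable", "MultiOmicsDataset", function(x) x@survival)
#' @rdname SyntheticCohort-class
#' @export
setMethod("survivalTable", "SyntheticCohort", function(x) x@dataset@survival)

#' @rdname GccaSolution-class
#' @param x a GccaSolution.
#' @export
setGeneric("sharedRepresentation",
           function(x) standardGeneric("sharedRepresentation"))
#' @rdname GccaSolution-class
#' @export
setMethod("sharedRepresentation", "GccaSolution", function(x) x@G)

#' @rdname GccaSolution-class
#' @export
setGeneric("gccaObjective", function(x) standardGeneric("gccaObjective"))
#' @rdname GccaSolution-class
#' @export
setMethod("gccaObjective", "GccaSolution", function(x) x@objective)

#' @rdname ClusterModel-class
#' @param x a ClusterModel or SyntheticCohort.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ClusterModel-class
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
#' @rdname SyntheticCohort-class
#' @param x a SyntheticCohort.
#' @export
setMethod("clusterLabels", "SyntheticCohort", function(x) x@trueLabels)

setMethod("show", "OmicsView", function(object) {
  cat(sprintf("OmicsView '%s': %d features x %d samples (%d missing entries)\n",
              object@name, nrow(object@values), ncol(object@values),
              sum(object@missingMask)))
})

setMethod("show", "MultiOmicsDataset", function(object) {
  cat(sprintf("MultiOmicsDataset: %d views, %d samples in universe\n",
              length(object@views), nrow(object@presence)))
  for (i in seq_along(object@views)) {
    v <- object@views[[i]]
    cat(sprintf("  [%d] %-12s %6d features, %4d/%4d samples present\n", i,
                v@name, nrow(v@values), sum(object@presence[, i]),
                nrow(object@presence)))
  }
  cat(sprintf("  survival: %d records (%d events), unit = %s\n",
              length(object@survival@sampleIds), sum(object@survival@event),
              object@survival@timeUnit))
})

setMethod("show", "GccaSolution", function(object) {
  cat(sprintf(
    "GccaSolution: r = %d, N = %d, %d views, objective = %.6g\n",
    nrow(object@G), ncol(object@G), length(object@U), object@objective))
})

setMethod("show", "TrainedDgcca", function(object) {
  cat(sprintf(
    "TrainedDgcca: %d views, %d epochs, final objective = %.6g\n",
    length(object@networks), length(object@lossHistory),
    object@finalSolution@objective))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel: k = %d, inertia = %.4g, avg silhouette = %.3f, CH = %.3f\n",
    object@k, object@inertia, object@avgSilhouette, object@chScore))
})

setMethod("show", "SurvivalComparison", function(object) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.4g\n",
              object@chi2, object@df, object@pValue))
})

setMethod("show", "SubtypeClassifier", function(object) {
  cat(sprintf(
    "SubtypeClassifier: %d features, %d classes, CV accuracy = %.3f, AUC = %.3f\n",
    length(object@features), length(object@classLevels), object@cvAccuracy,
    object@cvAuc))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d samples, %d planted clusters\n",
              length(object@trueLabels), length(unique(object@trueLabels))))
  show(object@dataset)
})
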