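## Orchestration of the two pipeline stages and the simulator: a single YAML
## config, deterministic seeding, persisted intermediates and INFO logging of
## every data-dependent count (features dropped, coordinates selected, ...).

#' Read (or build) a pipeline configuration
#'
#' A single YAML file drives every stage. Every default equals the reference
#' constant where one exists: 500/100 network nodes, L1 1e-3, L2 1e-4,
#' covariance ridge 1e-6, r = 100, 20 epochs, Cox alpha 0.05, k-means 100
#' restarts / 2000 iterations, 10-fold CV with 10 repeats, search budget 50.
#'
#' @param path optional YAML file; values found there override the defaults.
#' @param ... further overrides (named, nested lists merged shallowly).
#' @return nested configuration list.
#' @export
pipelineConfig <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    outdir = "pipeline_out",
    views = list(),                # name -> path
    survival = NULL,
    annotation = NULL,             # optional promoter annotation TSV
    preprocess = list(featureFrac = 0.2, sampleFrac = 0.2,
                      zerosAsMissing = list(), knnK = 10L,
                      logTransform = list(), logOffset = 1),
    network = list(hiddenUnits = 500L, outputUnits = 100L,
                   activation = "relu", l1 = 0.001, l2 = 0.0001),
    gcca = list(embeddingDim = 100L, viewRank = 100L, covReg = 1e-6,
                epochs = 20L, learningRate = 0.001),
    clustering = list(alpha = 0.05, kRange = 2:6, nInit = 100L,
                      maxIter = 2000L),
    classifier = list(view = 1L, nBins = 30L, folds = 10L, repeats = 10L,
                      budget = 50L, numTrees = 300L),
    simulation = list())
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  dots <- list(...)
  if (length(dots)) cfg <- modifyList(cfg, dots)
  cfg
}

.log <- function(...) message("[", format(Sys.time(), "%H:%M:%S"), "] ",
                              sprintf(...))

# load + preprocess all configured views; returns a MultiOmicsDataset
.loadDataset <- function(config) {
  if (is.null(config$survival) || !file.exists(config$survival))
    stop("survival file missing: ", config$survival)
  for (p in unlist(config$views))
    if (!file.exists(p)) stop("view file missing: ", p)
  surv <- readSurvivalTable(config$survival)
  pp <- config$preprocess
  viewList <- lapply(names(config$views), function(nm) {
    v <- readOmicsView(config$views[[nm]], nm)
    if (!is.null(config$annotation) && isTRUE(pp$collapse[[nm]])) {
      annot <- readPromoterAnnotation(config$annotation)
      v <- averagePromoterProbes(v, annot)
    }
    zam <- isTRUE(pp$zerosAsMissing[[nm]])
    v <- filterMissingness(v, pp$featureFrac, pp$sampleFrac,
                           zerosAsMissing = zam, verbose = TRUE)
    if (any(v@missingMask)) v <- knnImpute(v, pp$knnK)
    if (isTRUE(pp$logTransform[[nm]])) v <- logTransform(v, pp$logOffset)
    v
  })
  assembleDataset(viewList, surv)
}

#' Run the clustering stage end to end
#'
#' io/preprocessing -> deep-GCCA training -> embedding -> Cox filtering ->
#' k selection -> log-rank report. All intermediates are written under
#' \code{config$outdir}: the embedding, the per-coordinate Cox results, the
#' per-k diagnostics, the cluster assignments, the Kaplan-Meier curves and a
#' plain-text survival report.
#'
#' @param config a [pipelineConfig()].
#' @param dataset optional pre-assembled [MultiOmicsDataset-class] (bypasses
#'   the file-reading path; used by [runSimulate()]-based workflows).
#' @return list: dataset, model, embedding, coxResults, selection, clusters
#'   (the chosen [ClusterModel-class]), survivalComparison, paths.
#' @export
runClusterStage <- function(config, dataset = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dataset)) dataset <- .loadDataset(config)
  .log("clustering stage: %d views, %d samples, seed %d",
       length(dataset@views), nrow(dataset@presence), config$seed)
  netCfg <- do.call(viewNetworkConfig, config$network)
  gCfg <- do.call(gccaConfig, c(config$gcca, list(seed = config$seed)))
  model <- trainDgcca(dataset, netCfg, gCfg)
  emb <- embedSamples(model, dataset)
  flt <- filterEmbedding(emb, dataset@survival, config$clustering$alpha)
  .log("Cox filter: %d / %d coordinates selected at alpha = %g",
       sum(flt$results$selected), ncol(emb), config$clustering$alpha)
  sel <- selectK(flt$embedding, config$clustering$kRange,
                 nInit = config$clustering$nInit,
                 maxIter = config$clustering$maxIter, seed = config$seed)
  best <- sel$models[[paste0("k", sel$kBest)]]
  cmp <- logrankGroups(best@labels, dataset@survival)
  .log("selected k = %d; log-rank chi2 = %.4g (df %d), p = %.4g",
       sel$kBest, cmp@chi2, cmp@df, cmp@pValue)

  paths <- list(
    embedding = file.path(config$outdir, "embedding.tsv"),
    cox = file.path(config$outdir, "cox_filter.tsv"),
    diagnostics = file.path(config$outdir, "cluster_diagnostics.tsv"),
    assignments = file.path(config$outdir, "assignments.tsv"),
    km = file.path(config$outdir, "km_curves.tsv"),
    report = file.path(config$outdir, "survival_report.txt"))
  write.table(data.frame(sample_id = rownames(emb), emb), paths$embedding,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(flt$results, paths$cox, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sel$diagnostics, paths$diagnostics, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = rownames(emb), subtype = best@labels),
              paths$assignments, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cmp@kmCurves, paths$km, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sprintf("log-rank chi2 = %.10g\ndf = %d\np = %.10g\nk = %d",
                     cmp@chi2, cmp@df, cmp@pValue, sel$kBest), paths$report)
  list(dataset = dataset, model = model, embedding = emb,
       coxResults = flt$results, selection = sel, clusters = best,
       survivalComparison = cmp, paths = paths)
}

#' Run the classification stage on discovered subtypes
#'
#' Restricts the chosen training view to features shared with an external
#' reference (when given), median-scales, standardizes, fits the training
#' bins, selects features by RF-RFE and trains the tuned boosted-tree
#' classifier. The classifier archive is saved as RDS under
#' \code{config$outdir}.
#'
#' @param config a [pipelineConfig()].
#' @param dataset the training [MultiOmicsDataset-class].
#' @param assignments named vector (or data.frame sample_id/subtype) of
#'   subtype labels covering all samples present in the chosen view.
#' @param externalFeatures optional feature ids of the external platform; the
#'   classifier is trained on the intersection.
#' @return list: classifier ([SubtypeClassifier-class]), selection
#'   ([FeatureSelection-class]), paths.
#' @export
runClassifyStage <- function(config, dataset, assignments,
                             externalFeatures = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(assignments))
    assignments <- setNames(assignments$subtype, assignments$sample_id)
  cc <- config$classifier
  view <- dataset@views[[cc$view]]
  unknown <- setdiff(sampleIds(view), names(assignments))
  if (length(unknown))
    stop("samples without a subtype assignment: ",
         paste(unknown, collapse = ", "))
  feats <- featureIds(view)
  if (!is.null(externalFeatures)) {
    feats <- intersectFeatures(feats, externalFeatures)
    .log("feature intersection with external platform: %d / %d retained",
         length(feats), nrow(view@values))
  }
  x <- t(view@values[feats, , drop = FALSE])
  y <- factor(assignments[rownames(x)])
  scaler <- fitScaler(x)
  z <- standardizeExternal(x, scaler)
  bins <- fitBins(z, cc$nBins)
  b <- applyBins(bins, z)
  .log("RF-RFE on %d features, %d samples (%d-fold x %d)", ncol(b), nrow(b),
       cc$folds, cc$repeats)
  selection <- rfRfeSelect(b, y, folds = cc$folds, repeats = cc$repeats,
                           numTrees = cc$numTrees, seed = config$seed)
  .log("selected %d features; tuning over %d configurations",
       selection@chosenN, cc$budget)
  bsel <- b[, selection@chosenFeatures, drop = FALSE]
  clf <- tuneTrainClassifier(bsel, y, folds = cc$folds, budget = cc$budget,
                             seed = config$seed, scaler = scaler, bins = bins)
  .log("CV accuracy = %.4f, AUC = %.4f", clf@cvAccuracy, clf@cvAuc)
  paths <- list(archive = file.path(config$outdir, "classifier.rds"),
                metrics = file.path(config$outdir, "cv_metrics.txt"),
                curve = file.path(config$outdir, "rfe_curve.tsv"))
  saveRDS(clf, paths$archive)
  writeLines(sprintf("accuracy = %.10g\nauc = %.10g\nn_features = %d",
                     clf@cvAccuracy, clf@cvAuc, selection@chosenN),
             paths$metrics)
  write.table(selection@cvCurve, paths$curve, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(classifier = clf, selection = selection, paths = paths)
}

#' Validate a trained classifier on an external cohort
#'
#' Predicts subtypes for the external view through the stored preprocessing
#' chain; when external survival is supplied, quantifies the prognostic
#' separation of the predicted labels with the log-rank test.
#'
#' @param config a [pipelineConfig()].
#' @param classifier a [SubtypeClassifier-class] (or path to its RDS archive).
#' @param externalView an [OmicsView-class] measured on the external platform.
#' @param externalSurvival optional [SurvivalTable-class] for the external
#'   cohort.
#' @return list: predictions (data.frame), survivalComparison (or NULL),
#'   paths.
#' @export
runValidateStage <- function(config, classifier, externalView,
                             externalSurvival = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(classifier)) classifier <- readRDS(classifier)
  preds <- predictSubtypes(classifier, externalView)
  paths <- list(predictions = file.path(config$outdir, "predictions.tsv"))
  write.table(preds, paths$predictions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cmp <- NULL
  if (!is.null(externalSurvival)) {
    idx <- match(preds$sample_id, externalSurvival@sampleIds)
    surv <- SurvivalTable(preds$sample_id, externalSurvival@time[idx],
                          externalSurvival@event[idx],
                          externalSurvival@timeUnit)
    cmp <- logrankGroups(preds$subtype, surv)
    paths$report <- file.path(config$outdir, "validation_survival.txt")
    writeLines(sprintf("log-rank chi2 = %.10g\ndf = %d\np = %.10g",
                       cmp@chi2, cmp@df, cmp@pValue), paths$report)
    .log("external log-rank p = %.4g", cmp@pValue)
  }
  list(predictions = preds, survivalComparison = cmp, paths = paths)
}

#' Simulate a cohort (and optional external cohort) to disk
#'
#' @param config a [pipelineConfig()]; \code{config$simulation} holds
#'   [simulationConfig()] overrides, plus optional \code{external = TRUE}
#'   and platform-shift settings under \code{shift}.
#' @return list: cohort, external (or NULL), paths.
#' @export
runSimulate <- function(config) {
  simArgs <- config$simulation
  shift <- simArgs$shift; simArgs$shift <- NULL
  wantExternal <- isTRUE(simArgs$external); simArgs$external <- NULL
  simArgs$seed <- config$seed
  cfg <- do.call(simulationConfig, simArgs)
  cohort <- simulateCohort(cfg)
  paths <- writeCohort(cohort, config$outdir)
  external <- NULL
  if (wantExternal) {
    external <- do.call(simulatePlatformShift,
                        c(list(cohort = cohort), shift,
                          list(seed = config$seed + 1L)))
    extDir <- file.path(config$outdir, "external")
    dir.create(extDir, showWarnings = FALSE, recursive = TRUE)
    paths$external_view <- file.path(extDir, "external_view.tsv")
    writeOmicsView(external$view, paths$external_view)
    paths$external_survival <- file.path(extDir, "survival.tsv")
    writeSurvivalTable(external$survival, paths$external_survival)
    paths$external_truth <- file.path(extDir, "truth.tsv")
    write.table(data.frame(sample_id = names(external$labels),
                           cluster = external$labels),
                paths$external_truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  manifest <- file.path(config$outdir, "manifest.yaml")
  yaml::write_yaml(list(seed = config$seed, files = paths), manifest)
  paths$manifest <- manifest
  list(cohort = cohort, external = external, paths = paths)
}
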