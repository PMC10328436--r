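#' Read a features x samples matrix into an OmicsView
#'
#' Expects a tab-separated file whose first row holds the sample identifiers
#' and whose first column holds the feature identifiers. Empty cells, "NA",
#' and non-finite values are flagged as missing. Gzipped files are accepted.
#'
#' @param path path to the TSV (optionally .gz).
#' @param name label for the modality.
#' @return an [OmicsView-class].
#' @export
readOmicsView <- function(path, name = basename(path)) {
  con <- file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 2L)
    stop("malformed header in '", path, "': need a header row and >= 1 feature row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) < 1L || any(!nzchar(samples)))
    stop("malformed header in '", path, "': empty sample id")
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncell <- lengths(body)
  # a trailing empty cell is dropped by strsplit; restore it
  short <- ncell == length(samples) & endsWith(lines[-1], "\t")
  body[short] <- lapply(body[short], function(x) c(x, ""))
  ncell[short] <- ncell[short] + 1L
  bad <- which(ncell != length(samples) + 1L)
  if (length(bad))
    stop(sprintf("non-rectangular row at line %d (%d cells, expected %d)",
                 bad[1] + 1L, ncell[bad[1]], length(samples) + 1L))
  feats <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(feats))
    stop("duplicate feature id(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  vals <- vapply(body, function(x) {
    suppressWarnings(as.numeric(replace(x[-1], !nzchar(x[-1]), NA)))
  }, numeric(length(samples)))
  vals <- matrix(t(vals), nrow = length(feats),
                 dimnames = list(feats, samples))
  OmicsView(name, vals)
}

#' Write an OmicsView as the TSV format readOmicsView expects
#'
#' Missing entries are written as "NA". Round-tripping through
#' \code{writeOmicsView} and [readOmicsView()] reproduces values exactly
#' (full double precision is written).
#'
#' @param view an [OmicsView-class].
#' @param path output path.
#' @export
writeOmicsView <- function(view, path) {
  v <- view@values
  v[view@missingMask] <- NA
  df <- data.frame(feature_id = rownames(v),
                   format(as.data.frame(v), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(v)] <- "NA"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table (sample_id, time, event)
#'
#' @param path TSV with columns \code{sample_id}, \code{time}, \code{event}.
#' @param timeUnit unit label recorded on the table.
#' @return a [SurvivalTable-class].
#' @export
readSurvivalTable <- function(path, timeUnit = "days") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  SurvivalTable(df$sample_id, df$time, df$event, timeUnit)
}

#' Write a survival table as TSV
#' @param survival a [SurvivalTable-class].
#' @param path output path.
#' @export
writeSurvivalTable <- function(survival, path) {
  write.table(data.frame(sample_id = survival@sampleIds,
                         time = survival@time, event = survival@event),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a promoter annotation table (probe_id, gene_id, region)
#'
#' Only probes annotated to the promoter regions TSS200 or TSS1500 (within
#' 200 / 1500 bp upstream of a transcription start site) are retained; each
#' probe must map to exactly one (gene, region) entry.
#'
#' @param path TSV with columns \code{probe_id}, \code{gene_id}, \code{region}.
#' @return data.frame with those three columns.
#' @export
readPromoterAnnotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_id", "region")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  df <- df[df$region %in% c("TSS200", "TSS1500"), need]
  if (anyDuplicated(df$probe_id))
    stop("probe(s) with more than one annotation entry: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  df
}

#' Collapse methylation probes to gene promoters by averaging beta-values
#'
#' Probes mapping to the TSS200/TSS1500 promoter region of a gene are
#' averaged (arithmetic mean, ignoring missing entries) into one beta-value
#' per gene. Probes without an annotation entry are dropped.
#'
#' @param view an [OmicsView-class] of probe-level beta-values in \[0, 1\].
#' @param annot annotation data.frame from [readPromoterAnnotation()].
#' @return an [OmicsView-class] with one feature per gene.
#' @export
averagePromoterProbes <- function(view, annot) {
  keep <- intersect(rownames(view@values), annot$probe_id)
  if (length(keep) == 0L)
    stop("no probes in the view are covered by the annotation")
  gene <- annot$gene_id[match(keep, annot$probe_id)]
  v <- view@values[keep, , drop = FALSE]
  v[view@missingMask[keep, , drop = FALSE]] <- NA
  genes <- unique(gene)
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  for (g in genes) {
    block <- v[gene == g, , drop = FALSE]
    out[g, ] <- colMeans(block, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  OmicsView(view@name, out)
}

#' Drop features, then samples, exceeding a missingness fraction
#'
#' Two fixed-order passes: features whose missing (or zero, when
#' \code{zerosAsMissing}) fraction exceeds \code{featureFrac} are dropped
#' first; sample fractions are then recomputed over the surviving features
#' and samples exceeding \code{sampleFrac} are dropped. Defaults implement
#' the 20\% rule commonly applied to TCGA-style matrices.
#'
#' @param view an [OmicsView-class].
#' @param featureFrac maximum tolerated missing fraction per feature.
#' @param sampleFrac maximum tolerated missing fraction per sample.
#' @param zerosAsMissing count exact zeros as missing (sensible for
#'   count-derived views; leave FALSE for beta-values, where 0 is a value).
#' @param verbose log the number of features/samples dropped.
#' @return the filtered [OmicsView-class].
#' @export
filterMissingness <- function(view, featureFrac = 0.2, sampleFrac = 0.2,
                              zerosAsMissing = FALSE, verbose = FALSE) {
  stopifnot(featureFrac >= 0, featureFrac <= 1,
            sampleFrac >= 0, sampleFrac <= 1)
  bad <- view@missingMask
  if (zerosAsMissing) bad <- bad | (!view@missingMask & view@values == 0)
  keepF <- rowMeans(bad) <= featureFrac
  if (!any(keepF))
    stop("all features removed; consider relaxing featureFrac (", featureFrac, ")")
  bad <- bad[keepF, , drop = FALSE]
  keepS <- colMeans(bad) <= sampleFrac
  if (!any(keepS))
    stop("all samples removed; consider relaxing sampleFrac (", sampleFrac, ")")
  if (verbose)
    message(sprintf("filterMissingness[%s]: dropped %d/%d features, %d/%d samples",
                    view@name, sum(!keepF), length(keepF), sum(!keepS),
                    length(keepS)))
  OmicsView(view@name, view@values[keepF, keepS, drop = FALSE],
            view@missingMask[keepF, keepS, drop = FALSE])
}

#' Impute missing entries from the k nearest features
#'
#' For each feature with missing entries, the k nearest features (Euclidean
#' distance over co-observed samples, distances averaged per co-observed
#' sample to compare fairly across overlap sizes) that are observed at the
#' target sample are averaged. Observed cells are never modified.
#'
#' @param view an [OmicsView-class] (typically after [filterMissingness()]).
#' @param k number of neighbor features to average (default 10).
#' @return an [OmicsView-class] with an empty missing mask.
#' @export
knnImpute <- function(view, k = 10) {
  m <- view@missingMask
  if (!any(m)) return(view)
  v <- view@values
  v[m] <- NA
  needs <- which(rowSums(m) > 0L)
  obs <- !m
  too_few <- needs[rowSums(obs[needs, , drop = FALSE]) < 2L]
  if (length(too_few))
    stop("feature(s) with too few observed samples to compute distances: ",
         paste(rownames(v)[too_few], collapse = ", "))
  for (i in needs) {
    others <- setdiff(seq_len(nrow(v)), i)
    co <- obs[others, , drop = FALSE] & rep(obs[i, ], each = length(others))
    nco <- rowSums(co)
    diff2 <- (v[others, , drop = FALSE] -
                rep(v[i, ], each = length(others)))^2
    diff2[!co] <- 0
    d2 <- rowSums(diff2, na.rm = TRUE) / nco   # mean squared difference
    d2[nco == 0L] <- Inf
    ord <- others[order(d2, seq_along(d2))]
    for (s in which(m[i, ])) {
      cand <- ord[obs[ord, s]]
      if (length(cand) == 0L)
        stop("feature '", rownames(v)[i], "' has no observed neighbor at sample '",
             colnames(v)[s], "'")
      v[i, s] <- mean(v[head(cand, k), s])
    }
  }
  OmicsView(view@name, v)
}

#' Elementwise log2(value + offset) transform
#'
#' @param view an [OmicsView-class].
#' @param offset pseudo-count added before the log (default 1).
#' @return transformed [OmicsView-class].
#' @export
logTransform <- function(view, offset = 1) {
  v <- view@values
  ok <- !view@missingMask
  if (any(v[ok] + offset <= 0))
    stop("log transform undefined: value + offset <= 0 encountered")
  v[ok] <- log2(v[ok] + offset)
  OmicsView(view@name, v, view@missingMask)
}

#' Assemble aligned views and survival into a MultiOmicsDataset
#'
#' The sample universe is the union of the views' sample sets; samples
#' missing from a view are flagged absent in the presence mask rather than
#' dropped, so partially observed patients are retained.
#'
#' @param viewList list of [OmicsView-class] objects.
#' @param survival a [SurvivalTable-class]; must cover every sample that
#'   appears in any view.
#' @return a [MultiOmicsDataset-class].
#' @export
assembleDataset <- function(viewList, survival) {
  stopifnot(length(viewList) >= 1L)
  uni <- unique(unlist(lapply(viewList, function(v) colnames(v@values))))
  missing_surv <- setdiff(uni, survival@sampleIds)
  if (length(missing_surv))
    stop("sample(s) without a survival record: ",
         paste(missing_surv, collapse = ", "))
  presence <- vapply(viewList, function(v) uni %in% colnames(v@values),
                     logical(length(uni)))
  presence <- matrix(presence, nrow = length(uni),
                     dimnames = list(uni, vapply(viewList, viewName,
                                                 character(1))))
  idx <- match(uni, survival@sampleIds)
  surv <- SurvivalTable(uni, survival@time[idx], survival@event[idx],
                        survival@timeUnit)
  new("MultiOmicsDataset", views = viewList, presence = presence,
      survival = surv)
}
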