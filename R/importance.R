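## Selection-frequency feature importance: how often each feature type (and,
## for per-channel runs, each channel) appears in the final selected sets
## across training folds, expressed as a percentage of all selections.

## extract per-fold selected feature-name vectors from a CVResult or accept a
## plain list of character vectors
selectedSets <- function(x) {
  if (is(x, "CVResult")) x <- selectionLogs(x)
  sets <- lapply(x, function(l) if (is.list(l)) l$selected else l)
  sets <- Filter(function(s) length(s) > 0, sets)
  if (!length(sets)) stop("no selected feature sets available")
  sets
}

splitFeatureName <- function(names) {
  data.frame(channel = sub("\\.[^.]*$", "", names),
             type = sub("^.*\\.", "", names),
             stringsAsFactors = FALSE)
}

#' Feature-type importance from selection logs
#'
#' Counts how often each feature type was selected across the training folds
#' (summing over channels) and divides by the total number of selections, in
#' percent. Percentages sum to 100 per subject.
#'
#' @param logs a \code{CVResult} with SFS selection logs, or a list of
#'   per-fold character vectors of selected feature names ("channel.type").
#' @return named numeric, percent per feature type (all eight types, zeros
#'   included).
#' @export
importanceByFeatureType <- function(logs) {
  sets <- selectedSets(logs)
  types <- splitFeatureName(unlist(sets))$type
  out <- 100 * table(factor(types, levels = featureTypes())) / length(types)
  stats::setNames(as.numeric(out), featureTypes())
}

#' Channel importance from selection logs
#'
#' As \code{\link{importanceByFeatureType}} with the channel axis (summing
#' over feature types). Only defined for per-channel runs; surrogate-only
#' logs are rejected.
#'
#' @param logs see \code{\link{importanceByFeatureType}}.
#' @param montage channel names defining the axis (zeros included).
#' @return named numeric, percent per channel.
#' @export
importanceByChannel <- function(logs, montage) {
  sets <- selectedSets(logs)
  chans <- splitFeatureName(unlist(sets))$channel
  if (all(chans == "surrogate"))
    stop("channel importance is undefined for surrogate-only runs")
  unknown <- setdiff(unique(chans), montage)
  if (length(unknown))
    stop("selected features reference channels outside the montage: ",
         paste(unknown, collapse = ", "))
  out <- 100 * table(factor(chans, levels = montage)) / length(chans)
  stats::setNames(as.numeric(out), montage)
}

#' Aggregate importance tables across subjects
#'
#' Per-name mean and SD over all subjects or over the best half (the
#' ceiling(n/2) subjects with the highest mean cross-validated accuracy,
#' unless \code{bestN} is given).
#'
#' @param tables list of per-subject named percent vectors (identical names).
#' @param subset "all" or "best_half".
#' @param accuracies per-subject mean accuracies (required for best_half).
#' @param bestN size of the best-half subset.
#' @return data.frame(name, mean, sd) plus attribute \code{subjects} (the
#'   subject indices used).
#' @export
aggregateAcrossSubjects <- function(tables, subset = c("all", "best_half"),
                                    accuracies = NULL, bestN = NULL) {
  subset <- match.arg(subset)
  stopifnot(length(tables) >= 2)
  nms <- names(tables[[1]])
  if (!all(vapply(tables, function(t) identical(names(t), nms), logical(1))))
    stop("all subjects must share the same importance axis")
  use <- seq_along(tables)
  if (subset == "best_half") {
    if (is.null(accuracies) || length(accuracies) != length(tables))
      stop("best_half requires one accuracy per subject")
    if (is.null(bestN)) bestN <- ceiling(length(tables) / 2)
    if (bestN > length(tables)) stop("bestN exceeds the number of subjects")
    use <- order(-accuracies)[seq_len(bestN)]
  }
  m <- do.call(rbind, tables[use])
  out <- data.frame(name = nms, mean = colMeans(m), sd = apply(m, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "subjects") <- use
  out
}

## tiny deterministic polynomial hash of a character string (run manifests);
## double arithmetic stays exact (intermediates < 2^53)
configHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a report bundle from a pipeline run
#'
#' Writes chart-ready tables: per-subject accuracies with the chance line,
#' feature-type (and channel, when available) importance with mean and SD
#' across subjects, pooled row-normalized confusion matrices, grand-average
#' traces, rest-period variance summaries, and a run manifest (config hash,
#' seed, package version). Serialization is deterministic: identical inputs
#' give byte-identical bundles.
#'
#' @param run a pipeline run object from \code{\link{runPipeline}}.
#' @param outDir output directory (created if needed).
#' @param subset "all" or "best_half" for the importance aggregation.
#' @return \code{outDir}, invisibly.
#' @export
buildReport <- function(run, outDir, subset = c("all", "best_half")) {
  subset <- match.arg(subset)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  accs <- vapply(run$subjects, function(s) meanAccuracy(s$cv), numeric(1))
  accTab <- data.frame(
    subject = vapply(run$subjects, `[[`, character(1), "subjectId"),
    meanAccuracy = fmt(accs),
    sdAccuracy = fmt(vapply(run$subjects,
                            function(s) stats::sd(foldAccuracy(s$cv)), numeric(1))),
    chanceLevel = fmt(vapply(run$subjects,
                             function(s) chanceLevelOf(s$cv), numeric(1))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(accTab, file.path(outDir, "accuracy.csv"), row.names = FALSE,
                   quote = FALSE)
  impTabs <- Filter(Negate(is.null),
                    lapply(run$subjects, `[[`, "importanceType"))
  if (length(impTabs)) {
    if (length(impTabs) >= 2) {
      agg <- aggregateAcrossSubjects(impTabs, subset, accuracies = accs)
    } else {
      agg <- data.frame(name = names(impTabs[[1]]), mean = impTabs[[1]], sd = 0,
                        row.names = NULL, stringsAsFactors = FALSE)
    }
    agg$mean <- fmt(agg$mean)
    agg$sd <- fmt(agg$sd)
    utils::write.csv(agg, file.path(outDir, "importance_feature_type.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  chanTabs <- Filter(Negate(is.null),
                     lapply(run$subjects, `[[`, "importanceChannel"))
  if (length(chanTabs) >= 2) {
    aggC <- aggregateAcrossSubjects(chanTabs, subset,
                                    accuracies = accs[seq_along(chanTabs)])
    aggC$mean <- fmt(aggC$mean)
    aggC$sd <- fmt(aggC$sd)
    utils::write.csv(aggC, file.path(outDir, "importance_channel.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (s in run$subjects) {
    logs <- selectionLogs(s$cv)
    if (length(logs) && any(!vapply(logs, is.null, logical(1)))) {
      writeLines(jsonlite::toJSON(logs, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, null = "null"),
                 file.path(outDir, sprintf("selection_%s.json", s$subjectId)))
    }
    conf <- confusionMatrix(s$cv)
    confOut <- cbind(data.frame(True = rownames(conf)),
                     as.data.frame(apply(conf, 2, fmt)))
    utils::write.csv(confOut,
                     file.path(outDir, sprintf("confusion_%s.csv", s$subjectId)),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(run$grandAverage)) {
    ga <- as.data.frame(apply(run$grandAverage, 2, fmt))
    ga <- cbind(data.frame(class = rownames(run$grandAverage)), ga)
    utils::write.csv(ga, file.path(outDir, "grand_average.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(run$restVariance)) {
    rv <- data.frame(
      subject = vapply(run$restVariance, `[[`, character(1), "subject"),
      meanVariance = fmt(vapply(run$restVariance, `[[`, numeric(1), "meanVariance")),
      sdVariance = fmt(vapply(run$restVariance, `[[`, numeric(1), "sdVariance")),
      stringsAsFactors = FALSE
    )
    utils::write.csv(rv, file.path(outDir, "rest_variance.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  cfgJson <- jsonlite::toJSON(unclass(run$config), auto_unbox = TRUE,
                              digits = NA)
  manifest <- list(
    configHash = configHash(as.character(cfgJson)),
    seed = run$config$seed,
    task = run$config$task,
    mode = run$mode,
    onsetSource = if (run$mode == "imagined") "cue_trigger" else "force",
    nSubjects = length(run$subjects),
    package = "mrcpDecode",
    version = as.character(utils::packageVersion("mrcpDecode"))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outDir, "manifest.json"))
  summaryLines <- c(
    sprintf("Task: %s (%s), %d subject(s)", run$config$task, run$mode,
            length(run$subjects)),
    sprintf("Mean accuracy across subjects: %.4f (chance level %.4f)",
            mean(accs), chanceLevelOf(run$subjects[[1]]$cv)),
    if (length(impTabs))
      sprintf("Most selected feature type: %s",
              names(which.max(colMeansSafe(impTabs))))
  )
  writeLines(summaryLines, file.path(outDir, "summary.txt"))
  invisible(outDir)
}

colMeansSafe <- function(tabs) {
  m <- do.call(rbind, tabs)
  colMeans(m)
}
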