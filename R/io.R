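## Recording persistence (delimited numeric matrices + JSON sidecar) and the
## end-to-end pipeline driver.

#' Write / read a recording as delimited text with a JSON sidecar
#'
#' The directory holds \code{eeg.tsv} (samples x channels, header row),
#' \code{eog.tsv}, \code{force.tsv} and \code{meta.json} with subject id,
#' channels, sampling rates, triggers, labels, execution mode and MVC.
#' Numbers are written with 17 significant digits, so the round trip is
#' lossless for doubles.
#'
#' @param recording an \code{EEGRecording}.
#' @param path directory to write to / read from (created if needed).
#' @return \code{writeRecording}: \code{path}, invisibly.
#'   \code{readRecording}: the reconstructed \code{EEGRecording}.
#' @export
writeRecording <- function(recording, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  writeNumericTable(t(recording@eeg), recording@channels,
                    file.path(path, "eeg.tsv"))
  writeNumericTable(matrix(recording@eogFp1, ncol = 1), "FP1",
                    file.path(path, "eog.tsv"))
  writeNumericTable(matrix(recording@force, ncol = 1), "force",
                    file.path(path, "force.tsv"))
  meta <- list(
    subject_id = recording@subjectId,
    channels = recording@channels,
    fs_eeg = recording@fsEEG,
    fs_force = recording@fsForce,
    triggers = recording@triggers,
    labels = recording@labels,
    execution_mode = recording@executionMode,
    mvc = recording@mvc,
    rest_sec = recording@meta$restSec,
    cue_delay_sec = recording@meta$cueDelaySec
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "meta.json"))
  invisible(path)
}

writeNumericTable <- function(m, header, file) {
  ch <- apply(m, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(ch)) ch <- matrix(ch, ncol = ncol(m))
  colnames(ch) <- header
  data.table::fwrite(data.table::as.data.table(ch), file, sep = "\t",
                     quote = FALSE)
}

readNumericTable <- function(file) {
  dt <- data.table::fread(file, sep = "\t", header = TRUE,
                          colClasses = "numeric", data.table = FALSE)
  as.matrix(dt)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  metaFile <- file.path(path, "meta.json")
  if (!file.exists(metaFile)) stop("missing sidecar: ", metaFile)
  meta <- jsonlite::fromJSON(metaFile)
  required <- c("subject_id", "channels", "fs_eeg", "fs_force", "triggers",
                "labels", "execution_mode", "mvc")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sidecar schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  eeg <- readNumericTable(file.path(path, "eeg.tsv"))
  if (!identical(colnames(eeg), as.character(meta$channels)))
    stop("sidecar schema error: field 'channels' does not match eeg.tsv header")
  eog <- readNumericTable(file.path(path, "eog.tsv"))[, 1]
  force <- readNumericTable(file.path(path, "force.tsv"))[, 1]
  if (any(meta$triggers < 1) || any(meta$triggers > nrow(eeg)))
    stop("validation error: field 'triggers' outside the recorded signal")
  restSec <- if (!is.null(meta$rest_sec)) meta$rest_sec else NULL
  cueDelay <- if (!is.null(meta$cue_delay_sec)) meta$cue_delay_sec else NULL
  new("EEGRecording",
      eeg = t(eeg), channels = as.character(meta$channels),
      fsEEG = meta$fs_eeg, eogFp1 = eog, force = force,
      fsForce = meta$fs_force, triggers = as.integer(meta$triggers),
      labels = as.character(meta$labels), mvc = meta$mvc,
      executionMode = meta$execution_mode,
      subjectId = meta$subject_id,
      meta = Filter(Negate(is.null),
                    list(restSec = restSec, cueDelaySec = cueDelay)))
}

#' Write / read an epoch set as delimited text with a JSON sidecar
#'
#' \code{epochs.tsv} holds the samples x (trial, channel) matrix with
#' "trial<k>.<channel>" column names, \code{meta.json} the labels, onsets,
#' window, rate and subject, and \code{trial_log.csv} the per-trial
#' keep/reject/drop decisions.
#'
#' @param epochs an \code{EpochSet}.
#' @param path directory to write to / read from.
#' @return \code{writeEpochs}: \code{path}, invisibly; \code{readEpochs}: the
#'   reconstructed \code{EpochSet} (without the FP1 attribute).
#' @export
writeEpochs <- function(epochs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(2, 1, 3)), d[2], d[1] * d[3])
  header <- as.vector(outer(epochs@channels, seq_len(d[3]),
                            function(ch, tr) sprintf("trial%d.%s", tr, ch)))
  writeNumericTable(flat, header, file.path(path, "epochs.tsv"))
  meta <- list(subject_id = epochs@subjectId, channels = epochs@channels,
               fs = epochs@fs, window = epochs@window,
               labels = as.character(epochs@labels),
               onset_samples = epochs@onsetSamples)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "meta.json"))
  utils::write.csv(epochs@trialLog, file.path(path, "trial_log.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  flat <- readNumericTable(file.path(path, "epochs.tsv"))
  nCh <- length(meta$channels)
  nTr <- length(meta$labels)
  dat <- aperm(array(flat, dim = c(nrow(flat), nCh, nTr)), c(2, 1, 3))
  dimnames(dat) <- list(meta$channels, NULL, NULL)
  log <- utils::read.csv(file.path(path, "trial_log.csv"),
                         stringsAsFactors = FALSE)
  log$detail[is.na(log$detail)] <- ""
  new("EpochSet", data = dat, channels = as.character(meta$channels),
      fs = meta$fs, window = meta$window, labels = factor(meta$labels),
      onsetSamples = as.integer(meta$onset_samples),
      subjectId = meta$subject_id, trialLog = log)
}

#' Write a feature container as CSV
#'
#' One row per epoch; columns are the feature names, then \code{label},
#' \code{subject} and a \code{fold} placeholder column.
#'
#' @param features a \code{SummarizedExperiment} from
#'   \code{\link{extractFeatures}}.
#' @param file output CSV path.
#' @return \code{file}, invisibly.
#' @export
writeFeatureTable <- function(features, file) {
  ft <- featureTable(features)
  out <- as.data.frame(apply(ft$x, 2, function(col) sprintf("%.17g", col)))
  out$label <- ft$label
  out$subject <- ft$subject
  out$fold <- NA_integer_
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Run the full decoding pipeline on synthetic subjects
#'
#' For each subject: generate a recording, band-pass filter, (for the kinetic
#' task) reduce to the large-Laplacian surrogate channel, epoch [-2, 0) s
#' around the detected (executed) or cue-derived (imagined) onset, reject
#' EOG-contaminated epochs, extract the eight features per channel, and run
#' stratified 10-fold cross-validation with the requested reduction and the
#' task's classifier (LDA for grasp types, linear SVM for kinetic profiles).
#' Selection-frequency importance is tallied from the final per-fold selected
#' sets. The run is fully reproducible from the config seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param mode "executed" or "imagined".
#' @param k folds.
#' @param reduction "none", "sfs" or "pca".
#' @param classifier override the task default ("lda" or "linear_svm").
#' @param outDir when given, \code{\link{buildReport}} writes the bundle here.
#' @param restVarianceChannel channel for the rest-period variance summary
#'   (NULL to skip).
#' @return list(subjects, grandAverage, restVariance, config, mode); each
#'   subject entry has \code{cv}, \code{importanceType},
#'   \code{importanceChannel} (per-channel runs), \code{subjectId}, and the
#'   epoch trial log.
#' @export
runPipeline <- function(config, mode = c("executed", "imagined"), k = 10,
                        reduction = "sfs", classifier = NULL, outDir = NULL,
                        restVarianceChannel = "C3") {
  mode <- match.arg(mode)
  laplacian <- config$task == "kinetic"
  if (is.null(classifier))
    classifier <- if (config$task == "grasp") "lda" else "linear_svm"
  subjects <- vector("list", config$nSubjects)
  epochSets <- vector("list", config$nSubjects)
  restVar <- if (is.null(restVarianceChannel)) NULL else list()
  for (s in seq_len(config$nSubjects)) {
    rec <- generateRecording(config, subject = s, mode = mode)
    if (!is.null(restVarianceChannel))
      restVar[[s]] <- restVariance(rec, channel = restVarianceChannel)
    ep <- preprocessRecording(rec, laplacian = laplacian)
    fe <- extractFeatures(ep, mode = if (laplacian) "surrogate_only"
                          else "per_channel")
    cv <- runKfold(fe, k = k, reduction = reduction, classifier = classifier,
                   seed = (config$seed + 7 * s) %% 2147483647L)
    impT <- if (reduction == "sfs") importanceByFeatureType(cv) else NULL
    impC <- if (reduction == "sfs" && !laplacian)
      importanceByChannel(cv, config$montage) else NULL
    subjects[[s]] <- list(cv = cv, importanceType = impT,
                          importanceChannel = impC,
                          subjectId = rec@subjectId,
                          trialLog = trialLog(ep))
    epochSets[[s]] <- if (laplacian) NULL else ep
    rm(rec)
  }
  ga <- if (!laplacian) grandAverage(Filter(Negate(is.null), epochSets), "C3")
        else NULL
  run <- list(subjects = subjects, grandAverage = ga, restVariance = restVar,
              config = config, mode = mode)
  if (!is.null(outDir)) buildReport(run, outDir)
  run
}
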