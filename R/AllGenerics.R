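#' @rdname EEGRecording-class
#' @param object,x an \code{EEGRecording} or \code{EpochSet}
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname CVResult-class
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname CVResult-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

setMethod("channelNames", "EEGRecording", function(x) x@channels)
setMethod("channelNames", "EpochSet", function(x) x@channels)
setMethod("samplingRate", "EEGRecording", function(x) x@fsEEG)
setMethod("samplingRate", "EpochSet", function(x) x@fs)
setMethod("trialLabels", "EEGRecording", function(x) x@labels)
setMethod("trialLabels", "EpochSet", function(x) x@labels)
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
setMethod("nTrials", "EEGRecording", function(x) length(x@triggers))
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[3])

setMethod("meanAccuracy", "CVResult", function(x) mean(x@foldAccuracy))
setMethod("confusionMatrix", "CVResult", function(x) x@confusion)

#' @rdname EEGRecording-class
#' @export
trialLog <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@trialLog
}

#' @rdname EEGRecording-class
#' @export
epochData <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@data
}

#' @rdname CVResult-class
#' @export
foldAccuracy <- function(x) {
  stopifnot(is(x, "CVResult"))
  x@foldAccuracy
}

#' @rdname CVResult-class
#' @export
chanceLevelOf <- function(x) {
  stopifnot(is(x, "CVResult"))
  x@chanceLevel
}

#' @rdname CVResult-class
#' @export
selectionLogs <- function(x) {
  stopifnot(is(x, "CVResult"))
  x@selectionLogs
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s)\n", object@subjectId, object@executionMode))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@eeg), ncol(object@eeg), object@fsEEG,
              ncol(object@eeg) / object@fsEEG))
  cat(sprintf("  force: %d samples @ %g Hz; %d trials, classes: %s\n",
              length(object@force), object@fsForce, length(object@triggers),
              paste(levels(factor(object@labels)), collapse = ", ")))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet '%s': %d epochs x %d channels x %d samples @ %g Hz\n",
              object@subjectId, d[3], d[1], d[2], object@fs))
  cat(sprintf("  window [%g, %g) s; kept %d of %d trials\n",
              object@window[1], object@window[2], d[3], nrow(object@trialLog)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s, reduction=%s, classifier=%s)\n",
              object@regime, object@reduction, object@classifier))
  cat(sprintf("  accuracy %.3f +/- %.3f over %d folds; chance level %.3f\n",
              mean(object@foldAccuracy), stats::sd(object@foldAccuracy),
              length(object@foldAccuracy), object@chanceLevel))
})
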