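#' @import methods
NULL

#' Continuous multi-channel EEG recording with force and triggers
#'
#' Container for one subject's continuous recording of a cued grasp block:
#' monopolar EEG (microvolts, channels in rows of the 10-20 montage), the FP1
#' electrooculogram, the dynamometer force trace (fraction of MVC, sampled on
#' its own clock), per-trial cue-trigger sample indices on the EEG clock, and
#' per-trial class labels.
#'
#' @slot eeg numeric matrix, channels x samples, microvolts.
#' @slot channels character, channel names matching \code{rownames(eeg)}.
#' @slot fsEEG EEG/EOG sampling rate in Hz.
#' @slot eogFp1 numeric vector, FP1 EOG, same length and clock as the EEG.
#' @slot force numeric vector, force as fraction of MVC at \code{fsForce} Hz.
#' @slot fsForce force sampling rate in Hz.
#' @slot triggers integer vector, per-trial cue-onset sample indices (1-based,
#'   EEG clock), strictly increasing.
#' @slot labels character vector of per-trial class labels, one per trigger.
#' @slot mvc maximum voluntary contraction; 1 when force is pre-normalized.
#' @slot executionMode \code{"executed"} or \code{"imagined"}.
#' @slot subjectId subject identifier.
#' @slot meta list of free-form provenance (generator config, cue delay, ...).
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    eeg = "matrix",
    channels = "character",
    fsEEG = "numeric",
    eogFp1 = "numeric",
    force = "numeric",
    fsForce = "numeric",
    triggers = "integer",
    labels = "character",
    mvc = "numeric",
    executionMode = "character",
    subjectId = "character",
    meta = "list"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@eeg) != length(object@channels))
    msg <- c(msg, "nrow(eeg) must equal length(channels)")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel names must be unique")
  if (length(object@eogFp1) != ncol(object@eeg))
    msg <- c(msg, "eogFp1 must have one sample per EEG sample")
  if (object@fsEEG <= 0 || object@fsForce <= 0)
    msg <- c(msg, "sampling rates must be positive")
  if (length(object@triggers) != length(object@labels))
    msg <- c(msg, "one label per trigger required")
  if (length(object@triggers) > 1 && any(diff(object@triggers) <= 0))
    msg <- c(msg, "triggers must be strictly increasing")
  if (length(object@triggers) &&
      (min(object@triggers) < 1 || max(object@triggers) > ncol(object@eeg)))
    msg <- c(msg, "triggers must index into the EEG signal")
  if (!object@executionMode %in% c("executed", "imagined"))
    msg <- c(msg, "executionMode must be 'executed' or 'imagined'")
  if (length(msg)) msg else TRUE
})

#' Set of fixed-length premovement epochs
#'
#' Epochs are channel x sample x trial slices of a preprocessed recording,
#' cut over a fixed window relative to movement onset (half-open, onset sample
#' excluded). The trial log records every trial of the source recording with
#' its outcome, so trial accounting is conserved:
#' kept + rejected_eog + dropped_onset + dropped_edge = n trials.
#'
#' @slot data numeric array, channels x samples x trials (microvolts).
#' @slot channels character, channel names.
#' @slot fs sampling rate in Hz.
#' @slot window length-2 numeric, epoch window in seconds relative to onset.
#' @slot labels factor of class labels for the kept trials.
#' @slot onsetSamples integer, EEG-clock onset sample per kept trial.
#' @slot subjectId subject identifier.
#' @slot trialLog data.frame with columns trial, label, status, detail.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    channels = "character",
    fs = "numeric",
    window = "numeric",
    labels = "factor",
    onsetSamples = "integer",
    subjectId = "character",
    trialLog = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3)
    msg <- c(msg, "data must be a channels x samples x trials array")
  else {
    if (d[1] != length(object@channels))
      msg <- c(msg, "dim 1 must match channels")
    if (d[3] != length(object@labels))
      msg <- c(msg, "dim 3 must match labels")
    if (d[3] != length(object@onsetSamples))
      msg <- c(msg, "dim 3 must match onsetSamples")
    expected <- round(diff(object@window) * object@fs)
    if (d[2] != expected)
      msg <- c(msg, sprintf("epoch length %d != round(window span x fs) = %d",
                            d[2], expected))
  }
  if (any(!is.finite(object@data)))
    msg <- c(msg, "epochs must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' @slot foldAccuracy numeric, accuracy per fold (or per held-out subject).
#' @slot confusion numeric matrix, row-normalized confusion (rows = true class,
#'   columns = predicted class).
#' @slot counts integer matrix of raw pooled confusion counts.
#' @slot chanceLevel theoretical chance level for the pooled number of test
#'   trials at the result's significance level.
#' @slot regime \code{"kfold10"} or \code{"loso"}.
#' @slot reduction \code{"none"}, \code{"sfs"} or \code{"pca"}.
#' @slot classifier \code{"lda"} or \code{"linear_svm"}.
#' @slot selectionLogs list of per-fold selection logs (empty unless sfs/pca).
#'
#' @exportClass CVResult
setClass("CVResult",
  representation(
    foldAccuracy = "numeric",
    confusion = "matrix",
    counts = "matrix",
    chanceLevel = "numeric",
    regime = "character",
    reduction = "character",
    classifier = "character",
    selectionLogs = "list"
  )
)

setValidity("CVResult", function(object) {
  msg <- character()
  if (any(object@foldAccuracy < 0 | object@foldAccuracy > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  rs <- rowSums(object@confusion)
  bad <- abs(rs - 1) > 1e-9 & rowSums(object@counts) > 0
  if (any(bad))
    msg <- c(msg, "confusion rows with test samples must sum to 1")
  if (length(msg)) msg else TRUE
})
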