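## Preprocessing: zero-phase band-pass filtering, large-Laplacian surrogate
## channel, force-based movement-onset detection, epoching, and EOG rejection.

#' Band-pass filter specification
#'
#' Defaults follow the premovement-EEG convention: 0.05-45 Hz, order-2
#' Butterworth applied forward-backward (zero phase; effective order 4).
#'
#' @param lowCut,highCut band edges in Hz.
#' @param order Butterworth design order (before the forward-backward pass).
#' @param zeroPhase apply forward-backward.
#' @return list of class \code{FilterSpec}.
#' @export
filterSpec <- function(lowCut = 0.05, highCut = 45, order = 2, zeroPhase = TRUE) {
  stopifnot(lowCut > 0, lowCut < highCut, order >= 1)
  structure(list(lowCut = lowCut, highCut = highCut, order = order,
                 zeroPhase = zeroPhase), class = "FilterSpec")
}

#' Zero-phase Butterworth band-pass
#'
#' Designs an order-\code{spec$order} Butterworth band-pass and applies it
#' forward and backward (zero phase) with odd-reflection padding of length
#' 3 x filter length at both ends, so edge transients do not contaminate the
#' signal. Output length equals input length.
#'
#' @param x numeric vector (one channel) or channels x samples matrix.
#' @param spec a \code{\link{filterSpec}}.
#' @param fs sampling rate (Hz).
#' @return filtered signal, same shape as \code{x}.
#' @export
bandpassFilter <- function(x, spec = filterSpec(), fs) {
  stopifnot(spec$highCut < fs / 2)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, bandpassFilter, spec = spec, fs = fs))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  bt <- signal::butter(spec$order, c(spec$lowCut, spec$highCut) / (fs / 2),
                       type = "pass")
  b <- bt$b
  a <- bt$a
  npad <- 3 * max(length(a), length(b))
  n <- length(x)
  if (n <= npad)
    stop("signal too short for filter padding (need > ", npad, " samples)")
  padded <- c(2 * x[1] - x[(npad + 1):2],
              x,
              2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filter(b, a, padded)
  if (spec$zeroPhase) {
    y <- rev(signal::filter(b, a, rev(y)))
  }
  as.numeric(y[(npad + 1):(npad + n)])
}

#' Large-Laplacian surrogate channel centered on C3
#'
#' surrogate(t) = C3(t) minus the unweighted mean of the eight surrounding
#' electrodes F7, F3, Fz, T7, Cz, P7, P3, Pz.
#'
#' @param x channels x samples numeric matrix with channel rownames, or an
#'   \code{EEGRecording}.
#' @param center central channel name.
#' @param ring names of the surrounding electrodes.
#' @return numeric vector of surrogate samples.
#' @export
laplacianSurrogate <- function(x, center = "C3",
                               ring = c("F7", "F3", "Fz", "T7", "Cz",
                                        "P7", "P3", "Pz")) {
  if (is(x, "EEGRecording")) x <- x@eeg
  need <- c(center, ring)
  missing <- setdiff(need, rownames(x))
  if (length(missing))
    stop("missing channel(s) for Laplacian surrogate: ",
         paste(missing, collapse = ", "))
  as.numeric(x[center, ] - colMeans(x[ring, , drop = FALSE]))
}

#' Detect movement onset from the force trace
#'
#' The onset is the first sample s such that every sample in the 200 ms
#' window [s, s + windowMs) exceeds the baseline, where baseline =
#' mean + k x sd of the rest-phase force.
#'
#' @param force numeric force samples.
#' @param fsForce force sampling rate (Hz).
#' @param restSegment numeric rest-phase force samples defining the baseline.
#' @param windowMs moving-window width (ms).
#' @param baselineK baseline threshold constant k.
#' @return list(sample, time, baseline); sample is NA when no qualifying
#'   window exists (trial should be dropped).
#' @export
detectOnset <- function(force, fsForce, restSegment, windowMs = 200,
                        baselineK = 3) {
  stopifnot(length(restSegment) > 1)
  w <- round(windowMs / 1000 * fsForce)
  stopifnot(length(force) >= w)
  baseline <- mean(restSegment) + baselineK * stats::sd(restSegment)
  above <- force > baseline
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= w)
  if (!length(ok))
    return(list(sample = NA_integer_, time = NA_real_, baseline = baseline))
  s <- starts[ok[1]]
  list(sample = as.integer(s), time = (s - 1) / fsForce, baseline = baseline)
}

#' Per-trial movement onsets for a recording
#'
#' Executed recordings: the onset is detected from the force trace within
#' each trial's cue-to-cue interval (baseline from the initial rest phase)
#' and mapped to the EEG clock. Imagined recordings: the onset is the task
#' onset, cue trigger + cueDelaySec.
#'
#' @param recording an \code{EEGRecording}.
#' @param windowMs,baselineK see \code{\link{detectOnset}}.
#' @param cueDelaySec cue-to-task-onset delay; defaults to the recording's
#'   metadata (3 s if absent).
#' @return data.frame(trial, label, onsetSample, source, status) where
#'   onsetSample is on the EEG clock and status is "ok" or "no_onset".
#' @export
movementOnsets <- function(recording, windowMs = 200, baselineK = 3,
                           cueDelaySec = NULL) {
  fs <- recording@fsEEG
  fsF <- recording@fsForce
  nTr <- length(recording@triggers)
  if (is.null(cueDelaySec)) {
    cueDelaySec <- recording@meta$cueDelaySec
    if (is.null(cueDelaySec)) cueDelaySec <- 3
  }
  out <- data.frame(trial = seq_len(nTr), label = recording@labels,
                    onsetSample = NA_integer_, source = NA_character_,
                    status = "ok", stringsAsFactors = FALSE)
  if (recording@executionMode == "imagined") {
    out$onsetSample <- as.integer(recording@triggers + round(cueDelaySec * fs))
    out$source <- "cue_trigger"
    return(out)
  }
  restSec <- recording@meta$restSec
  if (is.null(restSec)) restSec <- 5
  rest <- recording@force[seq_len(max(2, round(restSec * fsF)))]
  trigTimes <- (recording@triggers - 1) / fs
  bounds <- c(trigTimes[-1], length(recording@force) / fsF)
  for (i in seq_len(nTr)) {
    from <- as.integer(round(trigTimes[i] * fsF) + 1L)
    to <- as.integer(min(length(recording@force), round(bounds[i] * fsF)))
    det <- detectOnset(recording@force[from:to], fsF, rest,
                       windowMs = windowMs, baselineK = baselineK)
    if (is.na(det$sample)) {
      out$status[i] <- "no_onset"
      out$source[i] <- "none"
    } else {
      forceSample <- from + det$sample - 1L
      out$onsetSample[i] <- forceToEEGSample(forceSample, fsF, fs)
      out$source[i] <- "force"
    }
  }
  out
}

#' Convert a force-clock sample index to the EEG clock
#'
#' Both clocks start at the same instant; sample 1 is t = 0 on each.
#'
#' @param forceSample 1-based force-clock sample index.
#' @param fsForce,fsEEG the two sampling rates (Hz).
#' @return 1-based EEG-clock sample index.
#' @export
forceToEEGSample <- function(forceSample, fsForce, fsEEG) {
  as.integer(round((forceSample - 1) / fsForce * fsEEG) + 1L)
}

#' Cut fixed premovement epochs from a recording
#'
#' Epochs cover the half-open window [window[1], window[2]) seconds relative
#' to onset: with the default [-2, 0) at 500 Hz each epoch is the 1000 samples
#' preceding (and excluding) the onset sample. Trials whose window would run
#' past the start of the recording are dropped and logged.
#'
#' @param recording an \code{EEGRecording} (filter it first: the band-pass is
#'   applied to the continuous signal, then epochs are cut).
#' @param onsets data.frame from \code{\link{movementOnsets}}, or an integer
#'   vector of EEG-clock onset samples (one per trial).
#' @param window epoch window (s) relative to onset, half-open.
#' @param channels channels to keep (default: all).
#' @return an \code{\link{EpochSet-class}}; FP1 epochs for EOG screening are
#'   attached as \code{attr(, "fp1")} (samples x trials).
#' @export
epochRecording <- function(recording, onsets = movementOnsets(recording),
                           window = c(-2, 0), channels = NULL) {
  fs <- recording@fsEEG
  if (is.numeric(onsets) && is.null(dim(onsets))) {
    onsets <- data.frame(trial = seq_along(onsets), label = recording@labels,
                         onsetSample = as.integer(onsets), source = "user",
                         status = ifelse(is.na(onsets), "no_onset", "ok"),
                         stringsAsFactors = FALSE)
  }
  stopifnot(nrow(onsets) == length(recording@triggers))
  if (is.null(channels)) channels <- recording@channels
  pre <- round(-window[1] * fs)
  post <- round(window[2] * fs)
  len <- pre + post
  n <- ncol(recording@eeg)
  log <- data.frame(trial = onsets$trial, label = onsets$label,
                    status = "kept", detail = "", stringsAsFactors = FALSE)
  log$status[onsets$status != "ok"] <- "dropped_onset"
  log$detail[onsets$status != "ok"] <- "no movement onset detected"
  keep <- logical(nrow(onsets))
  for (i in seq_len(nrow(onsets))) {
    if (log$status[i] != "kept") next
    o <- onsets$onsetSample[i]
    if (o - pre < 1 || o + post - 1 > n) {
      log$status[i] <- "dropped_edge"
      log$detail[i] <- "epoch window outside recording"
    } else keep[i] <- TRUE
  }
  kept <- which(keep)
  dat <- array(0, dim = c(length(channels), len, length(kept)),
               dimnames = list(channels, NULL, NULL))
  fp1 <- matrix(0, len, length(kept))
  for (j in seq_along(kept)) {
    o <- onsets$onsetSample[kept[j]]
    idx <- (o - pre):(o + post - 1L)
    dat[, , j] <- recording@eeg[channels, idx]
    fp1[, j] <- recording@eogFp1[idx]
  }
  es <- new("EpochSet", data = dat, channels = channels, fs = fs,
            window = window,
            labels = factor(onsets$label[kept]),
            onsetSamples = as.integer(onsets$onsetSample[kept]),
            subjectId = recording@subjectId, trialLog = log)
  attr(es, "fp1") <- fp1
  attr(es, "trialIds") <- kept
  es
}

#' Reject epochs with EOG contamination
#'
#' An epoch is removed iff the FP1 peak-peak amplitude within the epoch window
#' is strictly above the threshold (an epoch spanning exactly 125 uV is kept).
#'
#' @param epochs an \code{EpochSet} from \code{\link{epochRecording}}.
#' @param fp1 samples x trials matrix of FP1 epochs aligned with
#'   \code{epochs}; defaults to the matrix attached by
#'   \code{\link{epochRecording}}.
#' @param thresholdUv rejection threshold (uV peak-peak).
#' @return the surviving \code{EpochSet}; the trial log records per-trial
#'   decisions ("rejected_eog" with the measured peak-peak amplitude).
#' @export
rejectEOG <- function(epochs, fp1 = attr(epochs, "fp1"), thresholdUv = 125) {
  stopifnot(!is.null(fp1), ncol(fp1) == dim(epochs@data)[3])
  pp <- apply(fp1, 2, function(v) max(v) - min(v))
  keep <- pp <= thresholdUv
  log <- epochs@trialLog
  ids <- attr(epochs, "trialIds")
  if (is.null(ids)) ids <- which(log$status == "kept")
  rej <- ids[!keep]
  log$status[rej] <- "rejected_eog"
  log$detail[rej] <- sprintf("FP1 peak-peak %.1f uV > %g uV",
                             pp[!keep], thresholdUv)
  out <- new("EpochSet",
             data = epochs@data[, , keep, drop = FALSE],
             channels = epochs@channels, fs = epochs@fs,
             window = epochs@window,
             labels = droplevels(epochs@labels[keep]),
             onsetSamples = epochs@onsetSamples[keep],
             subjectId = epochs@subjectId, trialLog = log)
  attr(out, "fp1") <- fp1[, keep, drop = FALSE]
  attr(out, "trialIds") <- ids[keep]
  out
}

#' Filter, epoch and clean a recording in one call
#'
#' Applies the zero-phase band-pass to the continuous EEG and EOG, optionally
#' reduces the montage to the large-Laplacian surrogate channel, detects
#' movement onsets (force for executed, cue for imagined), cuts [-2, 0) s
#' epochs and rejects EOG-contaminated ones.
#'
#' @param recording an \code{EEGRecording}.
#' @param spec a \code{\link{filterSpec}}.
#' @param laplacian if TRUE the epochs contain the single surrogate channel.
#' @param thresholdUv EOG rejection threshold (uV peak-peak).
#' @param window epoch window (s).
#' @param windowMs,baselineK onset-detection parameters.
#' @return an \code{\link{EpochSet-class}}.
#' @export
preprocessRecording <- function(recording, spec = filterSpec(),
                                laplacian = FALSE, thresholdUv = 125,
                                window = c(-2, 0), windowMs = 200,
                                baselineK = 3) {
  fs <- recording@fsEEG
  if (laplacian) {
    ## the Laplacian and the band-pass are both linear and time-invariant, so
    ## the spatial filter is applied first and only the surrogate is filtered
    surr <- laplacianSurrogate(recording@eeg)
    recording@eeg <- matrix(surr, 1, length(surr),
                            dimnames = list("surrogate", NULL))
    recording@channels <- "surrogate"
  }
  recording@eeg <- bandpassFilter(recording@eeg, spec, fs)
  recording@eogFp1 <- bandpassFilter(recording@eogFp1, spec, fs)
  onsets <- movementOnsets(recording, windowMs = windowMs,
                           baselineK = baselineK)
  es <- epochRecording(recording, onsets, window = window)
  rejectEOG(es, thresholdUv = thresholdUv)
}

#' Per-class grand-average traces
#'
#' Pointwise mean across trials (pooled across subjects when a list of epoch
#' sets is given) per class, for one channel.
#'
#' @param epochs an \code{EpochSet} or a list of them.
#' @param channel channel name.
#' @return classes x samples numeric matrix.
#' @export
grandAverage <- function(epochs, channel = "C3") {
  if (is(epochs, "EpochSet")) epochs <- list(epochs)
  traces <- do.call(cbind, lapply(epochs, function(e) {
    e@data[match(channel, e@channels), , ]
  }))
  labs <- unlist(lapply(epochs, function(e) as.character(e@labels)))
  classes <- sort(unique(labs))
  if (!length(labs)) stop("no epochs")
  out <- t(vapply(classes, function(cl) rowMeans(traces[, labs == cl, drop = FALSE]),
                  numeric(nrow(traces))))
  rownames(out) <- classes
  out
}
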