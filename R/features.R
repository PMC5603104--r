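## Feature extraction: three MRCP-component time-domain features (readiness
## potential, negative slope, peak negativity) and the average power in the
## five classical EEG rhythm bands, per channel per epoch.

featureTypes <- function() c("RP", "NS", "PN", "delta", "theta", "alpha",
                             "beta", "gamma")

## sample indices of the half-open time interval [from, to) within an epoch
## whose window is win (s, relative to onset) at rate fs
windowIndices <- function(from, to, win, fs) {
  n <- round(diff(win) * fs)
  t <- win[1] + (seq_len(n) - 1) / fs
  which(t >= from - 1e-9 & t < to - 1e-9)
}

#' MRCP component amplitudes of one epoch trace
#'
#' \code{rpAmplitude}: mean amplitude over [-2, -0.5) s (readiness potential /
#' early CNV). \code{nsAmplitude}: mean over [-0.5, -0.15) s (negative slope /
#' late CNV). \code{peakNegativity}: minimum over the whole [-2, 0) s window
#' (motor potential; no sign forcing).
#'
#' @param trace numeric vector, one channel's epoch samples.
#' @param fs sampling rate (Hz).
#' @param window epoch window (s) relative to onset.
#' @return amplitude in uV.
#' @export
rpAmplitude <- function(trace, fs, window = c(-2, 0)) {
  idx <- windowIndices(-2, -0.5, window, fs)
  if (!length(idx) || max(idx) > length(trace))
    stop("epoch window does not cover [-2, -0.5) s")
  mean(trace[idx])
}

#' @rdname rpAmplitude
#' @export
nsAmplitude <- function(trace, fs, window = c(-2, 0)) {
  idx <- windowIndices(-0.5, -0.15, window, fs)
  if (!length(idx) || max(idx) > length(trace))
    stop("epoch window does not cover [-0.5, -0.15) s")
  mean(trace[idx])
}

#' @rdname rpAmplitude
#' @export
peakNegativity <- function(trace, fs, window = c(-2, 0)) {
  min(trace)
}

#' Hamming-window periodogram
#'
#' Single full-length periodogram with a Hamming taper: one-sided PSD in
#' uV^2/Hz, scaled so that summing PSD x bin width recovers the tapered
#' signal's power. With a 2 s epoch at 500 Hz the resolution is 0.5 Hz.
#'
#' @param trace numeric samples.
#' @param fs sampling rate (Hz).
#' @return list(freq, psd) over 0..Nyquist.
#' @export
hammingPeriodogram <- function(trace, fs) {
  n <- length(trace)
  k <- seq_len(n) - 1
  w <- 0.54 - 0.46 * cos(2 * pi * k / (n - 1))
  X <- stats::fft(trace * w)
  nHalf <- floor(n / 2) + 1
  psd <- (Mod(X[seq_len(nHalf)])^2) / (fs * sum(w^2))
  scale <- rep(2, nHalf)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nHalf] <- 1
  list(freq = (seq_len(nHalf) - 1) * fs / n, psd = psd * scale)
}

#' Average band power of one epoch trace
#'
#' Mean of the Hamming-periodogram PSD bins whose frequency f satisfies
#' low <= f < high (gamma: low <= f <= high, matching the 45 Hz low-pass).
#' The five bands partition the 0-45 Hz bins exactly.
#'
#' @param trace numeric samples (full epoch).
#' @param band one-row data.frame (or list) with \code{name}, \code{low},
#'   \code{high}; e.g. a row of \code{\link{bandDefinitions}}.
#' @param fs sampling rate (Hz).
#' @return mean PSD over the band's bins (uV^2/Hz).
#' @export
bandPower <- function(trace, band, fs) {
  if (band$high > fs / 2) stop("band extends beyond Nyquist")
  pg <- hammingPeriodogram(trace, fs)
  keep <- if (identical(band$name, "gamma")) {
    pg$freq >= band$low - 1e-9 & pg$freq <= band$high + 1e-9
  } else {
    pg$freq >= band$low - 1e-9 & pg$freq < band$high - 1e-9
  }
  mean(pg$psd[keep])
}

#' Extract the eight features per channel from an epoch set
#'
#' Per-channel mode emits 8 x n_channels features (200 for the 25-channel
#' montage); surrogate mode emits the 8 features of the single surrogate
#' channel. Feature names are "channel.type" with channels in montage order
#' and types in the fixed order RP, NS, PN, delta, theta, alpha, beta, gamma;
#' the ordering is identical for every epoch.
#'
#' @param epochs an \code{\link{EpochSet-class}}.
#' @param mode "per_channel" or "surrogate_only" (requires the single
#'   surrogate channel produced by \code{preprocessRecording(laplacian=TRUE)}).
#' @return a \code{SummarizedExperiment}: assay \code{features} is a feature x
#'   epoch matrix; \code{rowData} has \code{channel} and \code{type};
#'   \code{colData} has \code{label} and \code{subject}.
#' @export
extractFeatures <- function(epochs, mode = c("per_channel", "surrogate_only")) {
  mode <- match.arg(mode)
  chans <- epochs@channels
  if (mode == "surrogate_only") {
    if (!identical(chans, "surrogate"))
      stop("surrogate_only mode requires a single 'surrogate' channel ",
           "(use preprocessRecording(laplacian = TRUE))")
  }
  fs <- epochs@fs
  win <- epochs@window
  bands <- bandDefinitions()
  types <- featureTypes()
  nEp <- dim(epochs@data)[3]
  nCh <- length(chans)
  vals <- matrix(NA_real_, nCh * length(types), nEp)
  info <- data.frame(
    channel = rep(chans, each = length(types)),
    type = rep(types, nCh),
    stringsAsFactors = FALSE
  )
  rownames(vals) <- paste(info$channel, info$type, sep = ".")
  for (e in seq_len(nEp)) {
    for (c in seq_len(nCh)) {
      tr <- epochs@data[c, , e]
      pg <- hammingPeriodogram(tr, fs)
      bp <- vapply(seq_len(nrow(bands)), function(b) {
        keep <- if (bands$name[b] == "gamma") {
          pg$freq >= bands$low[b] - 1e-9 & pg$freq <= bands$high[b] + 1e-9
        } else {
          pg$freq >= bands$low[b] - 1e-9 & pg$freq < bands$high[b] - 1e-9
        }
        mean(pg$psd[keep])
      }, numeric(1))
      vals[(c - 1) * length(types) + seq_along(types), e] <-
        c(rpAmplitude(tr, fs, win), nsAmplitude(tr, fs, win),
          peakNegativity(tr, fs, win), bp)
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = vals),
    rowData = S4Vectors::DataFrame(info),
    colData = S4Vectors::DataFrame(
      label = as.character(epochs@labels),
      subject = rep(epochs@subjectId, nEp)
    )
  )
}

#' Feature matrix and labels from a feature container
#'
#' @param x a \code{SummarizedExperiment} from \code{\link{extractFeatures}}
#'   (or a plain epochs x features matrix, returned unchanged).
#' @return list(x = epochs x features matrix, label, subject).
#' @export
featureTable <- function(x) {
  if (is.matrix(x)) return(list(x = x, label = NULL, subject = NULL))
  m <- t(SummarizedExperiment::assay(x, "features"))
  cd <- SummarizedExperiment::colData(x)
  list(x = m, label = as.character(cd$label), subject = as.character(cd$subject))
}
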