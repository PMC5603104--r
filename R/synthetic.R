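## Synthetic cued-grasp EEG/force generator.
##
## Emulates the statistical structure the decoding pipeline assumes: a slow
## movement-related cortical potential (MRCP) over C3 with volume-conducted
## copies on neighboring 10-20 electrodes, class-dependent band-limited
## oscillatory power in the five classical EEG rhythms, 1/f + white background
## noise, occasional large blink transients on FP1, and dynamometer force
## traces realizing ramp-and-hold kinetic profiles or low-force grasps.

#' Kinetic profile and grasp-type task definitions
#'
#' The four kinetic profiles combine ramp speed (0.5 s vs 3 s) with force
#' target (20% vs 60% MVC); the three grasp types (palmar, lateral, pinch) all
#' ramp to ~5% MVC in 0.5 s.
#'
#' @return data.frame with columns \code{name}, \code{rampDuration} (s),
#'   \code{targetForce} (fraction of MVC).
#' @export
kineticProfiles <- function() {
  data.frame(
    name = c("F20", "F60", "S20", "S60"),
    rampDuration = c(0.5, 0.5, 3, 3),
    targetForce = c(0.2, 0.6, 0.2, 0.6),
    stringsAsFactors = FALSE
  )
}

#' @rdname kineticProfiles
#' @export
graspTypes <- function() {
  data.frame(
    name = c("palmar", "lateral", "pinch"),
    rampDuration = 0.5,
    targetForce = 0.05,
    stringsAsFactors = FALSE
  )
}

## 2-D schematic 10-20 coordinates (left hemisphere + midline subset used
## here); units are head-radius fractions, x negative = left, y positive =
## anterior. Only relative distances matter (volume-conduction kernel).
montageCoordinates <- function() {
  pos <- rbind(
    FP1 = c(-0.15, 0.85),
    F7 = c(-0.75, 0.50), F5 = c(-0.55, 0.50), F3 = c(-0.35, 0.50),
    F1 = c(-0.15, 0.50), Fz = c(0, 0.50),
    FT7 = c(-0.75, 0.25), FC5 = c(-0.55, 0.25), FC3 = c(-0.35, 0.25),
    FC1 = c(-0.15, 0.25), FCz = c(0, 0.25),
    T7 = c(-0.75, 0), C5 = c(-0.55, 0), C3 = c(-0.35, 0),
    C1 = c(-0.15, 0), Cz = c(0, 0),
    TP7 = c(-0.75, -0.25), CP5 = c(-0.55, -0.25), CP3 = c(-0.35, -0.25),
    CP1 = c(-0.15, -0.25), CPz = c(0, -0.25),
    P7 = c(-0.75, -0.50), P5 = c(-0.55, -0.50), P3 = c(-0.35, -0.50),
    P1 = c(-0.15, -0.50), Pz = c(0, -0.50)
  )
  colnames(pos) <- c("x", "y")
  pos
}

#' Default montages
#'
#' \code{graspMontage} is the 25-channel layout used for grasp-type blocks;
#' \code{kineticMontage} is the 20-channel sensorimotor grid extended with the
#' three lateral electrodes (F7, T7, P7) that complete the large-Laplacian
#' ring around C3. FP1 is recorded separately as the EOG channel.
#'
#' @return character vector of channel names.
#' @export
graspMontage <- function() {
  c("F7", "F5", "F3", "F1", "Fz", "FT7", "FC5", "FC3", "FC1", "FCz",
    "T7", "C5", "C3", "C1", "Cz", "TP7", "CP5", "CP3", "CP1", "CPz",
    "P7", "P5", "P3", "P1", "Pz")
}

#' @rdname graspMontage
#' @export
kineticMontage <- function() {
  c("F7", "F5", "F3", "F1", "Fz", "FC5", "FC3", "FC1", "FCz",
    "T7", "C5", "C3", "C1", "Cz", "CP5", "CP3", "CP1", "CPz",
    "P7", "P5", "P3", "P1", "Pz")
}

#' EEG rhythm band edges
#'
#' The five classical bands: delta 0-4, theta 4-7, alpha/mu 7-15, beta 15-30,
#' gamma 30-45 Hz. Bands are half-open [low, high) except gamma, whose upper
#' edge is inclusive to match the 45 Hz low-pass.
#'
#' @return data.frame with columns \code{name}, \code{low}, \code{high}.
#' @export
bandDefinitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(0, 4, 7, 15, 30),
    high = c(4, 7, 15, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic recording generator
#'
#' Defaults emulate the two study designs: \code{task = "grasp"} gives three
#' executed grasp types on the 25-channel montage; \code{task = "kinetic"}
#' gives four ramp-and-hold palmar contractions (executed or imagined) on the
#' Laplacian-capable montage. Class effects are multiplicative: per subject
#' and class, MRCP amplitude and band gains are scaled by log-normal effects
#' with log-sd \code{subjectEffectSd}; per trial, MRCP amplitude is scaled by
#' a log-normal with log-sd \code{trialJitterSd}.
#'
#' @param task "grasp" or "kinetic".
#' @param seed integer master seed; per-subject streams are derived from it.
#' @param nSubjects number of subjects the config describes.
#' @param nTrialsPerClass trials per class per subject.
#' @param montage channel names (must include C3 and, for Laplacian use, the
#'   ring F7, F3, Fz, T7, Cz, P7, P3, Pz).
#' @param fsEEG,fsForce sampling rates in Hz (EEG/EOG 500, force 2000).
#' @param classMrcp data.frame(class, amplitude uV (negative), onset s before
#'   movement, tau s rebound time constant).
#' @param classBandGain numeric matrix classes x bands of power gains applied
#'   within the premovement window.
#' @param bandRms baseline RMS amplitude (uV) of each rhythm at C3.
#' @param noiseExponent spectral exponent alpha of the 1/f^alpha background.
#' @param noiseScale RMS (uV) of the 1/f background per channel.
#' @param whiteScale RMS (uV) of additive white noise per channel.
#' @param eogRate per-trial blink probability.
#' @param eogAmplitude blink peak amplitude on FP1 (uV).
#' @param subjectEffectSd log-sd of between-subject class-parameter effects.
#' @param trialJitterSd log-sd of trial-to-trial MRCP amplitude variability.
#' @param imaginedScale MRCP amplitude scale for imagined-mode recordings.
#' @param interTrialSec cue-to-cue spacing (s).
#' @param restSec initial rest phase (s), used for the force baseline.
#' @param cueDelaySec delay from cue trigger to instructed movement onset (s).
#' @param onsetJitterSd sd (s) of the true movement onset around the cue.
#' @param forceNoiseSd sd of additive force noise (fraction of MVC).
#' @param spatialSigma width of the Gaussian volume-conduction kernel.
#' @return a validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(task = c("grasp", "kinetic"),
                            seed = 1L,
                            nSubjects = 1L,
                            nTrialsPerClass = if (task == "grasp") 25L else 40L,
                            montage = if (task == "grasp") graspMontage() else kineticMontage(),
                            fsEEG = 500,
                            fsForce = 2000,
                            classMrcp = NULL,
                            classBandGain = NULL,
                            bandRms = c(delta = 1.5, theta = 1.2, alpha = 1.5,
                                        beta = 1.0, gamma = 0.6),
                            noiseExponent = 1,
                            noiseScale = 3,
                            whiteScale = 1,
                            eogRate = 0.05,
                            eogAmplitude = 200,
                            subjectEffectSd = 0.2,
                            trialJitterSd = 0.2,
                            imaginedScale = 0.4,
                            interTrialSec = if (task == "grasp") 9 else 12,
                            restSec = 10,
                            cueDelaySec = 3,
                            onsetJitterSd = 0.1,
                            forceNoiseSd = 0.005,
                            spatialSigma = 0.3) {
  task <- match.arg(task)
  if (is.null(classMrcp)) {
    classMrcp <- if (task == "grasp") {
      data.frame(class = c("palmar", "lateral", "pinch"),
                 amplitude = c(-6, -5, -4),
                 onset = c(1.5, 1.4, 1.3),
                 tau = 0.5, stringsAsFactors = FALSE)
    } else {
      data.frame(class = c("F20", "F60", "S20", "S60"),
                 amplitude = c(-7, -9, -5, -6.5),
                 onset = c(1.5, 1.5, 2, 2),
                 tau = 0.5, stringsAsFactors = FALSE)
    }
  }
  bands <- bandDefinitions()$name
  if (is.null(classBandGain)) {
    cls <- classMrcp$class
    classBandGain <- matrix(1, length(cls), length(bands),
                            dimnames = list(cls, bands))
    if (task == "grasp") {
      classBandGain[, "alpha"] <- c(1.2, 1.0, 0.8)
      classBandGain[, "beta"] <- c(1.0, 1.2, 0.9)
    } else {
      classBandGain[, "alpha"] <- c(1.2, 1.5, 0.8, 1.0)
      classBandGain[, "beta"] <- c(1.0, 0.8, 1.3, 1.5)
    }
  }
  cfg <- list(task = task, seed = as.integer(seed), nSubjects = as.integer(nSubjects),
              nTrialsPerClass = as.integer(nTrialsPerClass), montage = montage,
              fsEEG = fsEEG, fsForce = fsForce, classMrcp = classMrcp,
              classBandGain = classBandGain, bandRms = bandRms,
              noiseExponent = noiseExponent, noiseScale = noiseScale,
              whiteScale = whiteScale, eogRate = eogRate,
              eogAmplitude = eogAmplitude, subjectEffectSd = subjectEffectSd,
              trialJitterSd = trialJitterSd, imaginedScale = imaginedScale,
              interTrialSec = interTrialSec, restSec = restSec,
              cueDelaySec = cueDelaySec, onsetJitterSd = onsetJitterSd,
              forceNoiseSd = forceNoiseSd, spatialSigma = spatialSigma)
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  stopifnot(
    cfg$fsEEG > 0, cfg$fsForce > 0,
    cfg$eogRate >= 0, cfg$eogRate <= 1,
    cfg$nTrialsPerClass >= 1,
    !anyDuplicated(cfg$montage),
    nrow(cfg$classMrcp) >= 1,
    all(cfg$classMrcp$onset > 0), all(cfg$classMrcp$tau > 0)
  )
  if (!"C3" %in% cfg$montage)
    stop("montage must include C3 (class signal and surrogate center)")
  if (!setequal(rownames(cfg$classBandGain), cfg$classMrcp$class))
    stop("classBandGain rows must match classMrcp classes")
  if (!all(bandDefinitions()$name %in% colnames(cfg$classBandGain)))
    stop("classBandGain must have a column per rhythm band")
  invisible(TRUE)
}

## 1/f^alpha Gaussian noise, unit RMS, synthesized in the frequency domain on
## an FFT-friendly length and truncated. exponent = 0 gives white noise.
spectralNoise <- function(n, fs, exponent) {
  m <- stats::nextn(n, c(2L, 3L))
  x <- stats::rnorm(m)
  if (exponent != 0) {
    X <- stats::fft(x)
    f <- (0:(m - 1)) * fs / m
    fEff <- pmin(f, fs - f)
    amp <- c(0, fEff[-1]^(-exponent / 2))
    x <- Re(stats::fft(X * amp, inverse = TRUE)) / m
  }
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

## Band-limited Gaussian noise, unit RMS, bins with low <= f <= high kept.
bandLimitedNoise <- function(n, fs, low, high) {
  m <- stats::nextn(n, c(2L, 3L))
  X <- stats::fft(stats::rnorm(m))
  f <- (0:(m - 1)) * fs / m
  fEff <- pmin(f, fs - f)
  keep <- fEff >= low & fEff <= high & fEff > 0
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

## Piecewise MRCP template on times t (s, relative to movement onset):
## flat baseline; linear negativity from -onset to 0.7*A at -0.15 s (readiness
## potential + negative slope); sharper dip to A at t = 0 (peak negativity);
## exponential rebound with time constant tau. Minimum is exactly A at t = 0.
mrcpTemplate <- function(t, amplitude, onset, tau) {
  y <- numeric(length(t))
  ramp <- t >= -onset & t < -0.15
  y[ramp] <- 0.7 * amplitude * (t[ramp] + onset) / (onset - 0.15)
  dip <- t >= -0.15 & t <= 0
  y[dip] <- 0.7 * amplitude + 0.3 * amplitude * (t[dip] + 0.15) / 0.15
  reb <- t > 0
  y[reb] <- amplitude * exp(-t[reb] / tau)
  y
}

## Gaussian volume-conduction weights from a source electrode to the montage.
spatialWeights <- function(montage, source = "C3", sigma = 0.3) {
  pos <- montageCoordinates()
  missing <- setdiff(c(montage, source), rownames(pos))
  if (length(missing))
    stop("no coordinates for channel(s): ", paste(missing, collapse = ", "))
  d2 <- (pos[montage, "x"] - pos[source, "x"])^2 +
    (pos[montage, "y"] - pos[source, "y"])^2
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- montage
  w
}

#' Force trace for a kinetic profile or grasp type
#'
#' Monotone linear ramp from 0 to \code{targetForce} over \code{rampDuration},
#' a hold phase, and a 0.5 s release, with optional additive Gaussian noise.
#' Imagined trials produce a flat (noise-only) trace.
#'
#' @param profile one-row data.frame (or list) with \code{targetForce} and
#'   \code{rampDuration}, e.g. a row of \code{kineticProfiles()}.
#' @param fsForce sampling rate (Hz).
#' @param holdDuration hold phase duration (s).
#' @param noiseSd sd of additive noise (fraction of MVC).
#' @param imagined if TRUE the trace is flat at 0 (plus noise).
#' @return numeric vector of force samples (fraction of MVC), starting at the
#'   movement onset sample (t = 0).
#' @export
generateForceTrace <- function(profile, fsForce, holdDuration = 3,
                               noiseSd = 0, imagined = FALSE) {
  stopifnot(fsForce > 0)
  release <- 0.5
  n <- round((profile$rampDuration + holdDuration + release) * fsForce) + 1
  t <- (seq_len(n) - 1) / fsForce
  if (imagined) {
    f <- numeric(n)
  } else {
    f <- profile$targetForce * pmin(t / profile$rampDuration, 1)
    rel <- t > profile$rampDuration + holdDuration
    f[rel] <- profile$targetForce *
      pmax(0, 1 - (t[rel] - profile$rampDuration - holdDuration) / release)
  }
  if (noiseSd > 0) f <- f + stats::rnorm(n, 0, noiseSd)
  f
}

#' Generate a synthetic recording for one subject
#'
#' Lays out \code{nTrialsPerClass} cued trials per class at
#' \code{interTrialSec} spacing after an initial rest phase, adds the MRCP
#' template (spatially spread from C3), class-gained rhythm oscillations, 1/f
#' and white background noise, blink artifacts at \code{eogRate}, and the
#' matching force trace. Deterministic given (config, subject, mode).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param subject integer subject index (drives the per-subject random stream
#'   and the subject-level class-parameter effects).
#' @param mode "executed" or "imagined" (imagined: no force, MRCP scaled by
#'   \code{imaginedScale}).
#' @return an \code{\link{EEGRecording-class}} object.
#' @export
generateRecording <- function(config, subject = 1L,
                              mode = c("executed", "imagined")) {
  mode <- match.arg(mode)
  validateSyntheticConfig(config)
  classes <- config$classMrcp$class
  if (length(classes) < 2)
    stop("at least 2 classes are required")
  seed <- (config$seed %% 100000L) * 20011L + subject * 211L +
    as.integer(mode == "imagined")
  seed <- seed %% 2147483647L
  withSeed(seed, generateRecordingImpl(config, subject, mode))
}

## run expr with a local RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

generateRecordingImpl <- function(config, subject, mode) {
  fs <- config$fsEEG
  fsF <- config$fsForce
  classes <- config$classMrcp$class
  nCls <- length(classes)
  nTrials <- nCls * config$nTrialsPerClass
  bands <- bandDefinitions()

  ## subject-level log-normal effects on class parameters
  mrcpEffect <- exp(stats::rnorm(nCls, 0, config$subjectEffectSd))
  names(mrcpEffect) <- classes
  bandEffect <- matrix(exp(stats::rnorm(nCls * nrow(bands), 0, config$subjectEffectSd)),
                       nCls, nrow(bands), dimnames = list(classes, bands$name))

  labels <- sample(rep(classes, config$nTrialsPerClass))
  tailSec <- config$cueDelaySec + 6
  durSec <- config$restSec + nTrials * config$interTrialSec + tailSec
  n <- round(durSec * fs)
  nF <- round(durSec * fsF)

  triggers <- as.integer(round((config$restSec +
    (seq_len(nTrials) - 1) * config$interTrialSec) * fs) + 1L)
  jitter <- pmax(pmin(stats::rnorm(nTrials, 0, config$onsetJitterSd), 0.3), -0.3)
  if (mode == "imagined") jitter[] <- 0
  onsetSamples <- as.integer(round(triggers + (config$cueDelaySec + jitter) * fs))

  montage <- config$montage
  nCh <- length(montage)
  w <- spatialWeights(montage, "C3", config$spatialSigma)

  ## background noise: independent 1/f + white per channel
  eeg <- matrix(0, nCh, n, dimnames = list(montage, NULL))
  for (ch in seq_len(nCh)) {
    bg <- 0
    if (config$noiseScale > 0)
      bg <- bg + config$noiseScale * spectralNoise(n, fs, config$noiseExponent)
    if (config$whiteScale > 0)
      bg <- bg + stats::rnorm(n, 0, config$whiteScale)
    if (!identical(bg, 0)) eeg[ch, ] <- bg
  }

  ## rhythm oscillations: one band-limited source per band at C3, gain applied
  ## within each trial's premovement window, spread by the conduction kernel
  preLen <- round(2 * fs)
  rhythm <- numeric(n)
  for (b in seq_len(nrow(bands))) {
    rms <- config$bandRms[[bands$name[b]]]
    if (rms <= 0) next
    src <- rms * bandLimitedNoise(n, fs, bands$low[b], bands$high[b])
    gainMask <- rep(1, n)
    for (i in seq_len(nTrials)) {
      o <- onsetSamples[i]
      idx <- max(1L, o - preLen):(o - 1L)
      g <- config$classBandGain[labels[i], bands$name[b]] *
        bandEffect[labels[i], bands$name[b]]
      gainMask[idx] <- sqrt(g)
    }
    rhythm <- rhythm + src * gainMask
  }

  ## MRCP template per trial
  mrcp <- numeric(n)
  mrcpScale <- if (mode == "imagined") config$imaginedScale else 1
  trialAmp <- exp(stats::rnorm(nTrials, 0, config$trialJitterSd))
  for (i in seq_len(nTrials)) {
    p <- config$classMrcp[match(labels[i], classes), ]
    o <- onsetSamples[i]
    span <- max(1L, o - as.integer(ceiling(p$onset * fs))):
      min(n, o + as.integer(ceiling(5 * p$tau * fs)))
    t <- (span - o) / fs
    amp <- p$amplitude * mrcpScale * mrcpEffect[labels[i]] * trialAmp[i]
    mrcp[span] <- mrcp[span] + mrcpTemplate(t, amp, p$onset, p$tau)
  }

  signal <- rhythm + mrcp
  eeg <- eeg + w %o% signal

  ## EOG channel: attenuated frontal background plus any blinks (added below)
  eog <- if (config$noiseScale > 0)
    config$noiseScale * spectralNoise(n, fs, max(config$noiseExponent, 1))
  else numeric(n)

  ## force trace
  force <- if (config$forceNoiseSd > 0) stats::rnorm(nF, 0, config$forceNoiseSd) else numeric(nF)
  if (mode == "executed") {
    profiles <- taskProfiles(config)
    for (i in seq_len(nTrials)) {
      p <- profiles[match(labels[i], profiles$name), ]
      tr <- generateForceTrace(p, fsF, holdDuration = 3, noiseSd = 0)
      oF <- as.integer(round((onsetSamples[i] - 1) / fs * fsF) + 1L)
      span <- oF:min(nF, oF + length(tr) - 1L)
      force[span] <- force[span] + tr[seq_along(span)]
    }
  }

  rec <- new("EEGRecording",
             eeg = eeg, channels = montage, fsEEG = fs,
             eogFp1 = eog, force = force, fsForce = fsF,
             triggers = triggers, labels = labels, mvc = 1,
             executionMode = mode,
             subjectId = sprintf("S%02d", subject),
             meta = list(restSec = config$restSec,
                         cueDelaySec = config$cueDelaySec,
                         interTrialSec = config$interTrialSec,
                         onsetSamples = onsetSamples,
                         task = config$task,
                         seedUsed = NA_integer_))
  if (config$eogRate > 0)
    rec <- injectEOG(rec, rate = config$eogRate,
                     amplitude = config$eogAmplitude)
  rec
}

taskProfiles <- function(config) {
  prof <- if (config$task == "grasp") graspTypes() else kineticProfiles()
  extra <- setdiff(config$classMrcp$class, prof$name)
  if (length(extra)) {
    prof <- rbind(prof, data.frame(name = extra, rampDuration = 0.5,
                                   targetForce = 0.2))
  }
  prof
}

#' Inject blink artifacts into a recording
#'
#' With probability \code{rate} per trial, adds a 300 ms raised-cosine blink
#' transient to the FP1 EOG channel within that trial's premovement window,
#' with attenuated copies on frontal EEG channels. The FP1 peak amplitude
#' (default 200 uV) guarantees peak-peak rejection at the 125 uV threshold.
#'
#' @param recording an \code{EEGRecording}.
#' @param rate per-trial blink probability in [0, 1].
#' @param amplitude blink peak amplitude on FP1 (uV).
#' @param seed optional integer; when given, blinks are drawn from a local
#'   seeded stream (otherwise the current RNG state is used).
#' @return the modified recording; \code{meta$blinkTrials} lists affected trials.
#' @export
injectEOG <- function(recording, rate, amplitude = 200, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(recording)
  run <- function() {
    fs <- recording@fsEEG
    nTr <- length(recording@triggers)
    hit <- stats::runif(nTr) < rate
    if (!any(hit)) return(recording)
    blinkLen <- round(0.3 * fs)
    pulse <- amplitude * sin(pi * seq(0, 1, length.out = blinkLen))^2
    cueDelay <- recording@meta$cueDelaySec
    if (is.null(cueDelay)) cueDelay <- 3
    frontal <- grepl("^F", recording@channels) & !grepl("^FC|^FT", recording@channels)
    wF <- rep(0, length(recording@channels))
    if (any(frontal)) {
      wAll <- spatialWeights(recording@channels, "FP1", 0.3)
      wF[frontal] <- 0.5 * wAll[frontal]
    }
    n <- ncol(recording@eeg)
    for (i in which(hit)) {
      onset <- recording@triggers[i] + round(cueDelay * fs)
      at <- onset - round(stats::runif(1, 0.2, 1.8) * fs)
      span <- max(1L, at):min(n, at + blinkLen - 1L)
      seg <- pulse[seq_along(span)]
      recording@eogFp1[span] <- recording@eogFp1[span] + seg
      recording@eeg[, span] <- recording@eeg[, span] + wF %o% seg
    }
    recording@meta$blinkTrials <- which(hit)
    recording
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}
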