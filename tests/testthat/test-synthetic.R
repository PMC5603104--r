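# Synthetic recording generator: determinism, MRCP geometry, force ramps,
# class band-power structure, blink injection, label balance.

test_that("generation is deterministic and labels are balanced", {
  cfg <- smallKineticConfig(seed = 7, nTrialsPerClass = 3)
  r1 <- generateRecording(cfg, subject = 1)
  r2 <- generateRecording(cfg, subject = 1)
  expect_identical(r1@eeg, r2@eeg)
  expect_identical(r1@eogFp1, r2@eogFp1)
  expect_identical(r1@force, r2@force)
  expect_identical(r1@labels, r2@labels)
  expect_true(all(table(r1@labels) == cfg$nTrialsPerClass))
  # different subject index gives a different realization
  r3 <- generateRecording(cfg, subject = 2)
  expect_false(identical(r1@eeg, r3@eeg))
})

test_that("noiseless MRCP attains its configured peak negativity at onset on C3", {
  cfg <- noiselessConfig(amplitude = -8)
  rec <- generateRecording(cfg, 1)
  o <- rec@meta$onsetSamples
  c3 <- rec@eeg["C3", ]
  expect_equal(min(c3), -8)
  expect_equal(unname(c3[o]), rep(-8, length(o)))
  # negativity begins at the configured onset-of-negativity time
  before <- o - round(1.6 * rec@fsEEG)
  expect_equal(unname(c3[before]), rep(0, length(o)))
  # volume conduction: neighbors carry attenuated copies, deeper than remote chans
  expect_lt(min(rec@eeg["C1", ]), -4)
  expect_gt(min(rec@eeg["P7", ]), min(rec@eeg["C1", ]))
})

test_that("increasing MRCP amplitude strictly deepens the averaged peak negativity", {
  peaks <- vapply(c(-4, -8, -12), function(a) {
    rec <- generateRecording(noiselessConfig(amplitude = a, seed = 9), 1)
    min(grandAverage(preprocessRecording(rec), "C3"))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("force traces realize the ramp profiles exactly", {
  f20 <- kineticProfiles()[1, ]
  tr <- generateForceTrace(f20, fsForce = 2000, noiseSd = 0)
  expect_equal(tr[0.5 * 2000 + 1], 0.20)
  expect_equal(tr[1], 0)
  # monotone over the ramp
  expect_true(all(diff(tr[1:(0.5 * 2000 + 1)]) >= 0))
  s60 <- kineticProfiles()[4, ]
  tr2 <- generateForceTrace(s60, fsForce = 2000, noiseSd = 0)
  expect_equal(tr2[1.5 * 2000 + 1], 0.6 * (1.5 / 3))  # linear interpolation
  # imagined: flat at zero
  expect_equal(max(abs(generateForceTrace(f20, 2000, imagined = TRUE))), 0)
})

test_that("imagined recordings have no force and onsets fall back to the cue", {
  cfg <- smallKineticConfig(seed = 3, nTrialsPerClass = 2, forceNoiseSd = 0.002)
  rec <- generateRecording(cfg, 1, mode = "imagined")
  expect_lt(max(abs(rec@force)), 0.05)
  on <- movementOnsets(rec)
  expect_true(all(on$source == "cue_trigger"))
  expect_equal(on$onsetSample,
               as.integer(rec@triggers + round(cfg$cueDelaySec * rec@fsEEG)))
})

test_that("class band-power gains show up at the configured power ratio", {
  # only the alpha rhythm present, gain 4x for F60 vs 1x for F20;
  # Monte-Carlo over 100 trials/class: mean alpha periodogram power ratio in [3, 5]
  gains <- matrix(1, 2, 5, dimnames = list(
    c("F20", "F60"), c("delta", "theta", "alpha", "beta", "gamma")))
  gains["F60", "alpha"] <- 4
  cfg <- syntheticConfig(
    "kinetic", seed = 11, nTrialsPerClass = 100, interTrialSec = 5,
    classMrcp = data.frame(class = c("F20", "F60"), amplitude = 0,
                           onset = 1.5, tau = 0.5),
    classBandGain = gains, noiseScale = 0, whiteScale = 0,
    bandRms = c(delta = 0, theta = 0, alpha = 1, beta = 0, gamma = 0),
    eogRate = 0, subjectEffectSd = 0, trialJitterSd = 0, onsetJitterSd = 0,
    forceNoiseSd = 0
  )
  rec <- generateRecording(cfg, 1)
  ep <- epochRecording(rec, rec@meta$onsetSamples)
  alpha <- bandDefinitions()[3, ]
  pow <- vapply(seq_len(nTrials(ep)), function(i) {
    bandPower(epochData(ep)["C3", , i], alpha, samplingRate(ep))
  }, numeric(1))
  ratio <- mean(pow[trialLabels(ep) == "F60"]) / mean(pow[trialLabels(ep) == "F20"])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("flat-spectrum background gives flat band powers", {
  # noise exponent 0 (white), no MRCP or rhythms: per-band mean power equal
  # across bands within Monte-Carlo error
  cfg <- syntheticConfig(
    "kinetic", seed = 21, nTrialsPerClass = 50, interTrialSec = 5,
    classMrcp = data.frame(class = c("F20", "F60"), amplitude = 0,
                           onset = 1.5, tau = 0.5),
    classBandGain = matrix(1, 2, 5, dimnames = list(
      c("F20", "F60"), c("delta", "theta", "alpha", "beta", "gamma"))),
    noiseExponent = 0, noiseScale = 1, whiteScale = 0,
    bandRms = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
    eogRate = 0, subjectEffectSd = 0, trialJitterSd = 0, onsetJitterSd = 0,
    forceNoiseSd = 0
  )
  rec <- generateRecording(cfg, 1)
  ep <- epochRecording(rec, rec@meta$onsetSamples)
  bands <- bandDefinitions()
  bandMeans <- vapply(seq_len(nrow(bands)), function(b) {
    mean(vapply(seq_len(nTrials(ep)), function(i) {
      bandPower(epochData(ep)["C3", , i], bands[b, ], samplingRate(ep))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(diff(range(bandMeans)) / mean(bandMeans), 0.15)
})

test_that("blink injection hits the requested fraction of trials and respects rate 0/1", {
  cfg <- smallKineticConfig(seed = 2, nTrialsPerClass = 2)
  rec <- generateRecording(cfg, 1)
  expect_identical(injectEOG(rec, rate = 0), rec)
  all_hit <- injectEOG(rec, rate = 1, amplitude = 200, seed = 4)
  ep <- preprocessRecording(all_hit)
  expect_equal(nTrials(ep), 0)
  expect_true(all(trialLog(ep)$status == "rejected_eog"))

  # rate 0.3 over many trials: rejected fraction within the binomial 99% CI
  # (imagined mode: cue-locked epochs, cheap small montage)
  cfgBig <- syntheticConfig(
    "kinetic", seed = 13, nTrialsPerClass = 200, interTrialSec = 5,
    montage = c("C3", "F3", "Fz", "Cz"), fsEEG = 250, fsForce = 1000,
    classMrcp = data.frame(class = c("F20", "F60"), amplitude = -5,
                           onset = 1.5, tau = 0.5),
    classBandGain = matrix(1, 2, 5, dimnames = list(
      c("F20", "F60"), c("delta", "theta", "alpha", "beta", "gamma"))),
    noiseScale = 1, whiteScale = 0.5, eogRate = 0, subjectEffectSd = 0,
    trialJitterSd = 0, onsetJitterSd = 0)
  recBig <- injectEOG(generateRecording(cfgBig, 1, mode = "imagined"),
                      rate = 0.3, amplitude = 200, seed = 99)
  epBig <- preprocessRecording(recBig)
  n <- 400
  frac <- sum(trialLog(epBig)$status == "rejected_eog") / n
  ci <- qbinom(c(0.005, 0.995), n, 0.3) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("generator rejects invalid configurations", {
  expect_error(syntheticConfig("kinetic", montage = c("F3", "Fz")), "C3")
  expect_error(syntheticConfig("kinetic", eogRate = 1.5))
  cfg <- smallKineticConfig()
  cfg$classMrcp <- cfg$classMrcp[1, ]
  cfg$classBandGain <- cfg$classBandGain[1, , drop = FALSE]
  expect_error(generateRecording(cfg, 1), "2 classes")
})
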