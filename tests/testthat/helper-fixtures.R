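# Shared fixture builders. Everything is generated in code; configs are kept
# small so the default test run stays fast.

# noise-free two-class kinetic config: deterministic MRCP geometry
noiselessConfig <- function(amplitude = -8, seed = 5, nTrialsPerClass = 3) {
  syntheticConfig(
    "kinetic", seed = seed, nTrialsPerClass = nTrialsPerClass,
    classMrcp = data.frame(class = c("F20", "F60"), amplitude = amplitude,
                           onset = 1.5, tau = 0.5),
    classBandGain = matrix(1, 2, 5, dimnames = list(
      c("F20", "F60"), c("delta", "theta", "alpha", "beta", "gamma"))),
    noiseScale = 0, whiteScale = 0,
    bandRms = c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0),
    eogRate = 0, subjectEffectSd = 0, trialJitterSd = 0, onsetJitterSd = 0,
    forceNoiseSd = 0
  )
}

# small low-noise kinetic config with clear class structure
smallKineticConfig <- function(seed = 1, nTrialsPerClass = 10, ...) {
  syntheticConfig("kinetic", seed = seed, nTrialsPerClass = nTrialsPerClass,
                  noiseScale = 1, whiteScale = 0.5, eogRate = 0,
                  subjectEffectSd = 0, trialJitterSd = 0.1, ...)
}

# strong-effect kinetic config: the 4 classes differ sharply in MRCP
# amplitude and in alpha/beta power
strongKineticConfig <- function(seed = 1, nTrialsPerClass = 40,
                                subjectEffectSd = 0, ...) {
  gains <- matrix(1, 4, 5, dimnames = list(
    c("F20", "F60", "S20", "S60"),
    c("delta", "theta", "alpha", "beta", "gamma")))
  gains[, "alpha"] <- c(1, 2, 0.5, 1.5)
  gains[, "beta"] <- c(1, 0.5, 2, 1.5)
  syntheticConfig(
    "kinetic", seed = seed, nTrialsPerClass = nTrialsPerClass,
    classMrcp = data.frame(class = c("F20", "F60", "S20", "S60"),
                           amplitude = c(-4, -10, -6, -8),
                           onset = c(1.5, 1.5, 2, 2), tau = 0.5),
    classBandGain = gains,
    noiseScale = 2, whiteScale = 1, eogRate = 0.05,
    subjectEffectSd = subjectEffectSd, trialJitterSd = 0.15, ...
  )
}

# Gaussian class data for classifier tests: g well-separated clusters
separableClasses <- function(n_per = 20, g = 3, p = 4, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(g * p), g, p) * sep
  x <- do.call(rbind, lapply(seq_len(g), function(k) {
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[k, ], "+")
  }))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(letters[seq_len(g)], each = n_per)))
}

# brute-force all-pairs Mann-Whitney U (independent oracle)
bruteU <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# O(n*w) sliding-window onset scan (independent oracle)
bruteOnset <- function(force, w, baseline) {
  for (s in seq_len(length(force) - w + 1)) {
    if (all(force[s:(s + w - 1)] > baseline)) return(s)
  }
  NA_integer_
}
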