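# Linear classifiers, k-fold / LOSO cross-validation, chance level,
# force-cue RMSE, Spearman correlation, rest-period variance.

test_that("both linear classifiers separate well-separated Gaussian classes", {
  d <- separableClasses(n_per = 20, g = 3, p = 4, sep = 8, seed = 31)
  for (kind in c("lda", "linear_svm")) {
    fit <- fitLinearClassifier(d$x, d$y, kind)
    expect_equal(mean(predict(fit, d$x) == d$y), 1)
  }
})

test_that("training on label-independent features yields chance-level test accuracy", {
  set.seed(32)
  n <- 400
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(letters[1:4], times = n / 4))
  fit <- fitLinearClassifier(x[1:200, ], y[1:200], "lda")
  acc <- mean(predict(fit, x[201:400, ]) == y[201:400])
  ci <- qbinom(c(0.025, 0.975), 200, 0.25) / 200
  expect_gte(acc, ci[1])
  expect_lte(acc, ci[2])
})

test_that("k-fold CV is deterministic, stratified, and exact on separable data", {
  d <- separableClasses(n_per = 20, g = 3, p = 4, sep = 8, seed = 33)
  colnames(d$x) <- paste0("C", 1:4, ".RP")
  cv1 <- runKfold(d$x, d$y, k = 10, reduction = "none", classifier = "lda",
                  seed = 5)
  cv2 <- runKfold(d$x, d$y, k = 10, reduction = "none", classifier = "lda",
                  seed = 5)
  expect_equal(meanAccuracy(cv1), 1)
  expect_identical(foldAccuracy(cv1), foldAccuracy(cv2))
  expect_identical(confusionMatrix(cv1), confusionMatrix(cv2))
  # confusion rows sum to one; diagonal mean equals accuracy (balanced test)
  expect_equal(unname(rowSums(confusionMatrix(cv1))), rep(1, 3))
  expect_equal(mean(diag(confusionMatrix(cv1))), meanAccuracy(cv1))
  # k = n reduces to leave-one-out: per-fold accuracy is 0 or 1
  cvLoo <- runKfold(d$x, d$y, k = nrow(d$x), reduction = "none",
                    classifier = "lda", seed = 5)
  expect_true(all(foldAccuracy(cvLoo) %in% c(0, 1)))
})

test_that("permuted labels give k-fold accuracy in the chance band", {
  set.seed(34)
  n <- 160
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- factor(rep(c("F20", "F60", "S20", "S60"), each = n / 4))
  accs <- vapply(1:20, function(i) {
    yy <- withr::with_seed(200 + i, sample(y))
    meanAccuracy(runKfold(x, yy, k = 10, reduction = "none",
                          classifier = "lda", seed = i))
  }, numeric(1))
  nTot <- 20 * n
  band <- 0.25 + c(-1, 1) * 1.96 * sqrt(0.25 * 0.75 / nTot)
  expect_gte(mean(accs), band[1] - 0.01)
  expect_lte(mean(accs), band[2] + 0.01)
})

test_that("chance level equals the exact binomial-sum oracle and is monotone", {
  # independent oracle: explicit tail sums from log binomial coefficients
  oracleChance <- function(n, k, alpha = 0.05) {
    p <- 1 / k
    tail <- function(a) {
      if (a > n) return(0)
      sum(exp(lchoose(n, a:n) + (a:n) * log(p) + (n - (a:n)) * log(1 - p)))
    }
    for (a in 0:n) if (tail(a) < alpha) return(min(a / n, 1))
    1
  }
  for (k in c(2, 3, 4)) {
    ours <- vapply(1:200, chanceLevel, numeric(1), nClasses = k)
    ref <- vapply(1:200, oracleChance, numeric(1), k = k)
    expect_equal(ours, ref)
    # decreasing on a coarse grid of n and toward 1/k in the limit (the exact
    # inverse-binomial level is not monotone sample-by-sample)
    coarse <- vapply(c(10, 20, 50, 100, 200), chanceLevel, numeric(1),
                     nClasses = k)
    expect_true(all(diff(coarse) < 0))
  }
  # more classes lower the level at fixed n
  expect_true(all(diff(vapply(2:6, function(k) chanceLevel(100, k),
                              numeric(1))) < 0))
  expect_equal(chanceLevel(1, 4), 1)
  # large-n limit approaches 1/k
  expect_lt(chanceLevel(100000, 4), 0.26)
})

test_that("LOSO transfers shared structure and fails on idiosyncratic subjects", {
  # cheap abstraction of the surrogate feature layout: 8 features whose class
  # means are shared across subjects (transferable) or drawn independently
  # per subject (idiosyncratic)
  mkSubject <- function(s, shared) {
    set.seed(1000 + s + 5000 * shared)
    n_per <- 15
    y <- factor(rep(c("F20", "F60", "S20", "S60"), each = n_per))
    centers <- if (shared) {
      withr::with_seed(77, matrix(rnorm(4 * 8, sd = 2), 4, 8))
    } else matrix(rnorm(4 * 8, sd = 2), 4, 8)
    x <- centers[as.integer(y), ] + matrix(rnorm(60 * 8), 60, 8)
    colnames(x) <- paste0("surrogate.f", 1:8)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(features = t(x)),
      colData = S4Vectors::DataFrame(label = as.character(y),
                                     subject = sprintf("S%02d", s)))
    se
  }
  shared <- lapply(1:6, mkSubject, shared = TRUE)
  cvS <- runLoso(shared, classifier = "linear_svm")
  expect_gt(meanAccuracy(cvS), chanceLevelOf(cvS))
  idio <- lapply(1:6, mkSubject, shared = FALSE)
  cvI <- runLoso(idio, classifier = "linear_svm")
  # per-subject accuracies are clustered, so judge "at chance" with a
  # t-interval across subjects rather than an iid binomial band
  a <- foldAccuracy(cvI)
  tstat <- (mean(a) - 0.25) / (sd(a) / sqrt(length(a)))
  expect_lt(abs(tstat), qt(0.995, length(a) - 1))
  expect_lt(meanAccuracy(cvI), meanAccuracy(cvS) - 0.2)
  expect_error(runLoso(shared[1:2]), "3 subjects")
})

test_that("force-cue RMSE matches closed forms and the brute-force sum", {
  cue <- generateForceTrace(kineticProfiles()[1, ], 100)
  expect_equal(forceCueRmse(cue, cue), 0)
  expect_equal(forceCueRmse(cue + 0.07, cue), 0.07)
  set.seed(36)
  a <- rnorm(500); b <- rnorm(500)
  expect_equal(forceCueRmse(a, b), sqrt(sum((a - b)^2) / 500))
  # resampling: a 2000 Hz force trace against a 100 Hz cue
  f2000 <- generateForceTrace(kineticProfiles()[1, ], 2000)
  expect_lt(forceCueRmse(f2000, cue, fsForce = 2000, fsCue = 100), 1e-9)
  expect_error(forceCueRmse(a, b[1:10]), "equal length")
})

test_that("Spearman correlation matches rank-then-Pearson with the t approximation", {
  expect_equal(spearmanCorrelation(1:10, exp(1:10))$rho, 1)
  expect_equal(spearmanCorrelation(1:10, -(1:10))$rho, -1)
  set.seed(37)
  x <- rnorm(20); y <- rnorm(20)
  ours <- spearmanCorrelation(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
})

test_that("rest-period variance behaves like a variance", {
  cfg <- smallKineticConfig(seed = 38, nTrialsPerClass = 3)
  rec <- generateRecording(cfg, 1)
  rv <- restVariance(rec, channel = "C3")
  ok <- rv$perTrial$status == "ok"
  expect_true(any(ok))
  expect_true(all(rv$perTrial$variance[ok] > 0))
  # doubling the signal quadruples the variance
  rec2 <- rec
  rec2@eeg <- rec@eeg * 2
  rv2 <- restVariance(rec2, channel = "C3")
  expect_equal(rv2$perTrial$variance[ok], 4 * rv$perTrial$variance[ok])
  # unit-variance white noise in a [-5, -3) window: 1000 samples, variance
  # concentrates in [0.9, 1.1]
  recW <- rec
  set.seed(39)
  recW@eeg["C3", ] <- rnorm(ncol(rec@eeg))
  rvW <- restVariance(recW, channel = "C3", spec = NULL)
  expect_true(all(rvW$perTrial$variance[ok] > 0.85 &
                    rvW$perTrial$variance[ok] < 1.15))
})
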