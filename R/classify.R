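## Classification and evaluation: linear classifiers (regularized LDA, linear
## SVM), stratified 10-fold and leave-one-subject-out cross-validation,
## binomial theoretical chance level, force-cue RMSE, Spearman correlation,
## and the rest-period variance analysis.

#' Fit a multiclass linear classifier
#'
#' \code{kind = "lda"}: the regularized pooled-covariance discriminant of
#' \code{\link{fitLDA}}. \code{kind = "linear_svm"}: linear-kernel SVM
#' (cost = 1, one-vs-one voting for multiclass, no internal scaling - scale
#' features beforehand). Both are deterministic given fixed inputs.
#'
#' @param x n x p numeric matrix.
#' @param y class labels (>= 2 classes, >= 2 samples each recommended).
#' @param kind "lda" or "linear_svm".
#' @param cost SVM regularization constant.
#' @return object of class \code{linearClassifier}.
#' @export
fitLinearClassifier <- function(x, y, kind = c("lda", "linear_svm"), cost = 1) {
  kind <- match.arg(kind)
  y <- factor(y)
  model <- if (kind == "lda") {
    fitLDA(x, y)
  } else {
    e1071::svm(as.matrix(x), y, kernel = "linear", cost = cost, scale = FALSE)
  }
  structure(list(kind = kind, model = model, levels = levels(y)),
            class = "linearClassifier")
}

#' @param object a \code{linearClassifier}.
#' @param newdata n x p matrix.
#' @param ... unused.
#' @rdname fitLinearClassifier
#' @export
predict.linearClassifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- if (object$kind == "lda") {
    predict(object$model, newdata)
  } else {
    predict(object$model, newdata)
  }
  factor(as.character(p), levels = object$levels)
}

## stratified fold assignment: within each class, shuffled samples are dealt
## round-robin into k folds
stratifiedFolds <- function(y, k, seed) {
  y <- factor(y)
  withSeed(seed, {
    fold <- integer(length(y))
    ## deal the class-blocked, within-class-shuffled sequence cyclically over
    ## folds so all k folds are used even when a class has fewer than k samples
    idx <- unlist(lapply(levels(y), function(cl) sample(which(y == cl))))
    fold[idx] <- rep_len(seq_len(k), length(idx))
    fold
  })
}

## non-stratified random partition; redrawn (up to 100 times) until every
## training fold contains every class
randomFolds <- function(y, k, seed) {
  y <- factor(y)
  withSeed(seed, {
    for (attempt in seq_len(100)) {
      fold <- sample(rep_len(seq_len(k), length(y)))
      ok <- all(vapply(seq_len(k), function(f) {
        nlevels(droplevels(y[fold != f])) == nlevels(y)
      }, logical(1)))
      if (ok) return(fold)
    }
    stop("could not draw a partition with all classes in every training fold")
  })
}

#' Stratified k-fold cross-validated classification
#'
#' Per fold: z-score with training statistics, run the chosen reduction on the
#' training part only (SFS selection or PCA projection; for PCA without an
#' explicit \code{nComponents}, SFS is run first and its selected-set size is
#' used, coupling the two as in the selection protocol), fit the classifier,
#' predict the held-out part. Accuracies are averaged across folds and the
#' pooled confusion matrix is row-normalized from raw counts.
#'
#' @param features a \code{SummarizedExperiment} from
#'   \code{\link{extractFeatures}}, or an epochs x features matrix.
#' @param labels class labels (taken from the container when omitted).
#' @param k number of folds.
#' @param reduction "none", "sfs" or "pca".
#' @param classifier "lda" or "linear_svm".
#' @param seed integer; fixes the partition (and nothing else).
#' @param nComponents PCA components (default: matched to SFS per fold).
#' @param stratified use stratified folds (default) or a literal random
#'   partition (redrawn if a training fold misses a class).
#' @param standardize z-score using training statistics per fold.
#' @param alpha significance level of the reported chance level.
#' @return a \code{\link{CVResult-class}}.
#' @export
runKfold <- function(features, labels = NULL, k = 10,
                     reduction = c("none", "sfs", "pca"),
                     classifier = c("lda", "linear_svm"),
                     seed = 1L, nComponents = NULL, stratified = TRUE,
                     standardize = TRUE, alpha = 0.05) {
  reduction <- match.arg(reduction)
  classifier <- match.arg(classifier)
  ft <- featureTable(features)
  x <- ft$x
  y <- factor(if (is.null(labels)) ft$label else labels)
  stopifnot(nrow(x) >= k, nlevels(y) >= 2)
  fold <- if (stratified) stratifiedFolds(y, k, seed) else randomFolds(y, k, seed)
  acc <- numeric(k)
  counts <- matrix(0L, nlevels(y), nlevels(y),
                   dimnames = list(levels(y), levels(y)))
  logs <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    ytr <- droplevels(y[tr])
    yte <- y[!tr]
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    sel <- NULL
    if (reduction == "sfs") {
      sel <- selectFeaturesSFS(xtr, ytr)
      xtr <- xtr[, sel$selected, drop = FALSE]
      xte <- xte[, sel$selected, drop = FALSE]
      logs[[f]] <- list(selected = sel$selected,
                        perClass = lapply(sel$perClass, `[[`, "accepted"),
                        trace = sel$merge$trace,
                        finalAccuracy = sel$merge$finalAccuracy)
    } else if (reduction == "pca") {
      nc <- nComponents
      if (is.null(nc)) {
        sel <- selectFeaturesSFS(xtr, ytr)
        nc <- length(sel$selected)
      }
      red <- pcaReduce(xtr, xte, nc)
      xtr <- red$train
      xte <- red$test
      logs[[f]] <- list(nComponents = red$nComponents,
                        selected = if (!is.null(sel)) sel$selected)
    }
    fit <- fitLinearClassifier(xtr, ytr, classifier)
    pred <- predict(fit, xte)
    acc[f] <- mean(pred == yte)
    for (i in seq_along(yte))
      counts[as.character(yte[i]), as.character(pred[i])] <-
        counts[as.character(yte[i]), as.character(pred[i])] + 1L
  }
  newCVResult(acc, counts, regime = "kfold10", reduction = reduction,
              classifier = classifier, logs = logs, alpha = alpha)
}

newCVResult <- function(acc, counts, regime, reduction, classifier, logs,
                        alpha = 0.05) {
  rs <- rowSums(counts)
  conf <- counts / ifelse(rs == 0, 1, rs)
  new("CVResult", foldAccuracy = acc, confusion = conf,
      counts = counts,
      chanceLevel = chanceLevel(sum(counts), nrow(counts), alpha),
      regime = regime, reduction = reduction, classifier = classifier,
      selectionLogs = logs)
}

#' Leave-one-subject-out cross-validation
#'
#' For each held-out subject the classifier is trained on all other subjects'
#' pooled epochs (full feature set, no per-subject selection; z-scored with
#' pooled training statistics) and evaluated on the held-out subject.
#'
#' @param features list of per-subject \code{SummarizedExperiment}s (all with
#'   the same feature layout), or one container whose \code{colData$subject}
#'   spans >= 3 subjects.
#' @param classifier "lda" or "linear_svm".
#' @param standardize z-score with pooled training-subject statistics.
#' @param alpha significance level of the reported chance level.
#' @return a \code{\link{CVResult-class}} with one fold per subject.
#' @export
runLoso <- function(features, classifier = c("lda", "linear_svm"),
                    standardize = TRUE, alpha = 0.05) {
  classifier <- match.arg(classifier)
  if (is.list(features) && !is(features, "SummarizedExperiment")) {
    tabs <- lapply(features, featureTable)
    layouts <- vapply(tabs, function(t) paste(colnames(t$x), collapse = "|"),
                      character(1))
    if (length(unique(layouts)) != 1)
      stop("all subjects must share the same feature layout")
    x <- do.call(rbind, lapply(tabs, `[[`, "x"))
    y <- unlist(lapply(tabs, `[[`, "label"))
    subj <- unlist(lapply(tabs, `[[`, "subject"))
  } else {
    ft <- featureTable(features)
    x <- ft$x
    y <- ft$label
    subj <- ft$subject
  }
  y <- factor(y)
  subjects <- unique(subj)
  if (length(subjects) < 3) stop("need at least 3 subjects")
  acc <- numeric(length(subjects))
  counts <- matrix(0L, nlevels(y), nlevels(y),
                   dimnames = list(levels(y), levels(y)))
  for (s in seq_along(subjects)) {
    te <- subj == subjects[s]
    xtr <- x[!te, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    fit <- fitLinearClassifier(xtr, y[!te], classifier)
    pred <- predict(fit, xte)
    yte <- y[te]
    acc[s] <- mean(pred == yte)
    for (i in seq_along(yte))
      counts[as.character(yte[i]), as.character(pred[i])] <-
        counts[as.character(yte[i]), as.character(pred[i])] + 1L
  }
  names(acc) <- subjects
  newCVResult(acc, counts, regime = "loso", reduction = "none",
              classifier = classifier, logs = list(), alpha = alpha)
}

#' Theoretical chance level of a classifier
#'
#' The smallest accuracy a/n whose one-sided binomial tail probability under
#' guessing (p = 1/nClasses) is below \code{alpha}. When no achievable
#' accuracy is significant (very small n) the level is capped at 1.
#'
#' @param nTest number of test trials.
#' @param nClasses number of classes.
#' @param alpha significance level.
#' @return chance level as a fraction in (0, 1].
#' @export
chanceLevel <- function(nTest, nClasses, alpha = 0.05) {
  stopifnot(nTest >= 1, nClasses >= 2)
  p <- 1 / nClasses
  a <- 0:nTest
  tail <- 1 - stats::pbinom(a - 1, nTest, p)
  ok <- which(tail < alpha)
  if (!length(ok)) return(1)
  min(a[ok[1]] / nTest, 1)
}

#' Root-mean-square error between produced force and the visual cue
#'
#' When sampling rates are supplied and differ, the force trace is linearly
#' resampled onto the cue's time grid first.
#'
#' @param force produced force samples (fraction of MVC).
#' @param cue cue trajectory samples (fraction of MVC).
#' @param fsForce,fsCue sampling rates (Hz); omit when already aligned.
#' @return RMSE (fraction of MVC).
#' @export
forceCueRmse <- function(force, cue, fsForce = NULL, fsCue = NULL) {
  if (!is.null(fsForce) && !is.null(fsCue) && fsForce != fsCue) {
    tF <- (seq_along(force) - 1) / fsForce
    tC <- (seq_along(cue) - 1) / fsCue
    force <- stats::approx(tF, force, xout = tC, rule = 2)$y
  }
  if (length(force) != length(cue))
    stop("force and cue must have equal length after resampling")
  sqrt(mean((force - cue)^2))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks; p from the t approximation with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list(rho, p).
#' @export
spearmanCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("Spearman correlation undefined for constant input")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
}

#' Rest-period variance analysis
#'
#' Extracts a pre-onset rest window (default [-5, -3) s) from one channel of
#' the band-pass filtered recording and computes the per-trial sample
#' variance, plus the subject's mean and SD across trials. Trials without
#' enough pre-onset data are skipped and logged.
#'
#' @param recording an \code{EEGRecording}.
#' @param window rest window (s) relative to movement onset, half-open.
#' @param channel channel to analyze.
#' @param spec band-pass specification applied before the analysis (NULL to
#'   skip filtering).
#' @param onsets optional onset data.frame (\code{\link{movementOnsets}}).
#' @return list(perTrial = data.frame(trial, label, variance, status),
#'   meanVariance, sdVariance, subject).
#' @export
restVariance <- function(recording, window = c(-5, -3), channel = "C3",
                         spec = filterSpec(), onsets = NULL) {
  fs <- recording@fsEEG
  trace <- recording@eeg[match(channel, recording@channels), ]
  if (!is.null(spec)) trace <- bandpassFilter(trace, spec, fs)
  if (is.null(onsets)) onsets <- movementOnsets(recording)
  pre <- round(-window[1] * fs)
  post <- round(window[2] * fs)
  out <- data.frame(trial = onsets$trial, label = onsets$label,
                    variance = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(onsets))) {
    if (onsets$status[i] != "ok") {
      out$status[i] <- "no_onset"
      next
    }
    o <- onsets$onsetSample[i]
    if (o - pre < 1) {
      out$status[i] <- "insufficient_preonset"
      next
    }
    idx <- (o - pre):(o + post - 1L)
    out$variance[i] <- stats::var(trace[idx])
  }
  ok <- out$status == "ok"
  list(perTrial = out,
       meanVariance = mean(out$variance[ok]),
       sdVariance = stats::sd(out$variance[ok]),
       subject = recording@subjectId)
}
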