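## Feature selection: Mann-Whitney u-statistic ranking, greedy sequential
## forward selection with an inner leave-one-out LDA, one-vs-rest candidate
## sets with a merge-and-reselect round, and the PCA alternative.

#' Mann-Whitney u-statistic and separability score
#'
#' U counts pairs (i, j) with x_i > y_j, ties counted 1/2 (midrank
#' computation). The separability score is direction-agnostic:
#' max(U, nx*ny - U), so a feature that is consistently *smaller* in the
#' target class ranks as high as one that is consistently larger. Two
#' identical samples give the minimum score nx*ny/2.
#'
#' @param x numeric values of the target class.
#' @param y numeric values of the rest.
#' @return list(U, score).
#' @export
uStatistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  list(U = U, score = max(U, nx * ny - U))
}

#' Rank features by u-statistic separability
#'
#' Features are ordered by decreasing separability score for the given binary
#' labelling; ties keep the original column order (stable), so montage /
#' feature-type order breaks ties. Constant columns are allowed and receive
#' the minimum score.
#'
#' @param x epochs x features numeric matrix with column names.
#' @param target logical vector (TRUE = target class) or a 2-level factor
#'   whose first level is the target.
#' @return data.frame(name, score, U) in rank order.
#' @export
rankFeatures <- function(x, target) {
  if (!is.logical(target)) target <- factor(target) == levels(factor(target))[1]
  if (sum(target) < 2 || sum(!target) < 2)
    stop("need at least 2 samples per class")
  stats <- apply(x, 2, function(col) {
    u <- uStatistic(col[target], col[!target])
    c(u$score, u$U)
  })
  ord <- order(-stats[1, ])
  data.frame(name = colnames(x)[ord], score = stats[1, ord], U = stats[2, ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regularized pooled-covariance linear discriminant
#'
#' Multiclass LDA with pooled within-class covariance regularized by
#' epsilon*I, epsilon = 1e-6 * trace(S) / p, and empirical class priors.
#' The regularization keeps leave-one-out fits on tiny training sets
#' invertible.
#'
#' @param x n x p numeric matrix.
#' @param y class labels.
#' @return an object of class \code{ldaFit} with a \code{predict} method.
#' @export
fitLDA <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  n <- nrow(x)
  p <- ncol(x)
  nk <- tabulate(as.integer(y), nlevels(y))
  if (any(nk < 1)) stop("every class needs at least one sample")
  M <- rowsum(x, y) / nk
  W <- crossprod(x - M[as.integer(y), , drop = FALSE])
  S <- W / max(1, n - nlevels(y))
  eps <- 1e-6 * sum(diag(S)) / p
  if (!is.finite(eps) || eps <= 0) eps <- 1e-8
  diag(S) <- diag(S) + eps
  B <- solve(S, t(M))
  structure(list(B = B, const = -0.5 * colSums(t(M) * B) + log(nk / n),
                 levels = levels(y)),
            class = "ldaFit")
}

#' @param object an \code{ldaFit}.
#' @param newdata n x p matrix.
#' @param ... unused.
#' @rdname fitLDA
#' @export
predict.ldaFit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sc <- sweep(newdata %*% object$B, 2, object$const, "+")
  factor(object$levels[max.col(sc, ties.method = "first")],
         levels = object$levels)
}

#' Leave-one-out LDA accuracy
#'
#' Exact leave-one-out cross-validated accuracy of \code{\link{fitLDA}},
#' computed with rank-one downdates of the class means and pooled scatter
#' (no refitting from scratch). A left-out sample whose class would vanish
#' from the training set counts as an error.
#'
#' @param x n x p numeric matrix.
#' @param y class labels.
#' @return accuracy in [0, 1].
#' @export
loocvAccuracyLDA <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  p <- ncol(x)
  g <- nlevels(y)
  yi <- as.integer(y)
  nk <- tabulate(yi, g)
  sums <- rowsum(x, y)
  M <- sums / nk
  W <- crossprod(x - M[yi, , drop = FALSE])
  denom <- max(1, n - 1 - g)
  correct <- 0L
  for (i in seq_len(n)) {
    k <- yi[i]
    if (nk[k] == 1L) next
    xi <- x[i, ]
    d <- xi - M[k, ]
    Wi <- W - (nk[k] / (nk[k] - 1)) * tcrossprod(d)
    Mi <- M
    Mi[k, ] <- (sums[k, ] - xi) / (nk[k] - 1)
    nki <- nk
    nki[k] <- nk[k] - 1L
    S <- Wi / denom
    eps <- 1e-6 * sum(diag(S)) / p
    if (!is.finite(eps) || eps <= 0) eps <- 1e-8
    diag(S) <- diag(S) + eps
    B <- try(solve(S, t(Mi)), silent = TRUE)
    if (inherits(B, "try-error")) next
    sc <- drop(xi %*% B) - 0.5 * colSums(t(Mi) * B) + log(nki / (n - 1))
    if (which.max(sc) == k) correct <- correct + 1L
  }
  correct / n
}

## greedy acceptance pass over features in rank order: start from the
## top-ranked feature, add each subsequent one iff the inner LOOCV accuracy
## strictly improves
greedyAccept <- function(x, y, rankedNames) {
  accepted <- rankedNames[1]
  best <- loocvAccuracyLDA(x[, accepted, drop = FALSE], y)
  trace <- best
  for (f in rankedNames[-1]) {
    acc <- loocvAccuracyLDA(x[, c(accepted, f), drop = FALSE], y)
    if (acc > best) {
      accepted <- c(accepted, f)
      best <- acc
      trace <- c(trace, acc)
    }
  }
  list(accepted = accepted, trace = trace, finalAccuracy = best)
}

#' One-vs-rest sequential forward selection
#'
#' Features are ranked by u-statistic separability of the binary problem,
#' then evaluated greedily in rank order: a feature is retained iff the
#' leave-one-out LDA accuracy on the current set plus the feature strictly
#' improves. All features are evaluated once.
#'
#' @param x epochs x features matrix (training fold only).
#' @param target binary labelling, see \code{\link{rankFeatures}}.
#' @return list(accepted, ranked, trace, finalAccuracy).
#' @export
sfsOneVsRest <- function(x, target) {
  if (nrow(x) < 4) stop("need at least 4 training samples")
  if (!is.logical(target)) target <- factor(target) == levels(factor(target))[1]
  ranked <- rankFeatures(x, target)
  yb <- factor(ifelse(target, "target", "rest"))
  res <- greedyAccept(x, yb, ranked$name)
  c(res, list(ranked = ranked))
}

#' Merge one-vs-rest candidate sets and reselect
#'
#' The union of the per-class candidate sets is re-ranked by the mean
#' one-vs-rest separability score across class problems and a second greedy
#' pass is run with the inner leave-one-out LDA now evaluating multiclass
#' accuracy.
#'
#' @param candidateSets list of character vectors of accepted feature names.
#' @param x epochs x features matrix (training fold only).
#' @param y multiclass labels.
#' @param meanScores named numeric, mean one-vs-rest score per feature.
#' @return list(selected, trace, finalAccuracy, union).
#' @export
mergeAndReselect <- function(candidateSets, x, y, meanScores) {
  union <- unique(unlist(candidateSets))
  union <- union[order(-meanScores[union])]
  if (length(union) == 1) {
    acc <- loocvAccuracyLDA(x[, union, drop = FALSE], factor(y))
    return(list(selected = union, trace = acc, finalAccuracy = acc,
                union = union))
  }
  res <- greedyAccept(x, factor(y), union)
  list(selected = res$accepted, trace = res$trace,
       finalAccuracy = res$finalAccuracy, union = union)
}

#' Full two-round sequential forward selection
#'
#' Runs \code{\link{sfsOneVsRest}} for each class against the pooled rest,
#' merges the candidate sets and reselects (\code{\link{mergeAndReselect}}).
#'
#' @param x epochs x features matrix (training fold only), with column names.
#' @param y multiclass labels (>= 2 classes).
#' @return list(selected, perClass, merge, meanScores); \code{perClass} is a
#'   per-class list of first-round logs.
#' @export
selectFeaturesSFS <- function(x, y) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  classes <- levels(y)
  perClass <- list()
  scoreMat <- matrix(NA_real_, length(classes), ncol(x),
                     dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    res <- sfsOneVsRest(x, y == cl)
    perClass[[cl]] <- res
    scoreMat[cl, res$ranked$name] <- res$ranked$score
  }
  meanScores <- colMeans(scoreMat)
  merge <- mergeAndReselect(lapply(perClass, `[[`, "accepted"), x, y, meanScores)
  list(selected = merge$selected, perClass = perClass, merge = merge,
       meanScores = meanScores)
}

#' PCA reduction fit on the training fold only
#'
#' Training rows are centered and projected on the leading principal axes;
#' test rows are centered with the *training* means and projected with the
#' training axes. When \code{nComponents} exceeds the rank of the centered
#' training data it is reduced to the rank (with a message).
#'
#' @param xTrain,xTest epochs x features matrices.
#' @param nComponents number of components to keep.
#' @return list(train, test, nComponents).
#' @export
pcaReduce <- function(xTrain, xTest, nComponents) {
  stopifnot(nComponents >= 1)
  pr <- stats::prcomp(xTrain, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-9)
  if (nComponents > rank) {
    message("nComponents reduced to rank ", rank)
    nComponents <- rank
  }
  rot <- pr$rotation[, seq_len(nComponents), drop = FALSE]
  list(
    train = pr$x[, seq_len(nComponents), drop = FALSE],
    test = sweep(as.matrix(xTest), 2, pr$center) %*% rot,
    nComponents = nComponents
  )
}
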