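# u-statistic ranking, sequential forward selection, merge-and-reselect, PCA.

test_that("u-statistic matches the brute-force all-pairs count", {
  u <- uStatistic(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u$U, 0)
  expect_equal(u$score, 9)
  u2 <- uStatistic(c(1, 3), c(2, 4))
  expect_equal(u2$U, 1)
  expect_equal(u2$score, 3)
  # identical samples: minimum separability n^2/2
  u3 <- uStatistic(1:5, 1:5)
  expect_equal(u3$U, 12.5)
  expect_equal(u3$score, 12.5)
  set.seed(20)
  for (i in 1:200) {
    x <- sample(round(rnorm(sample(2:8, 1)), 1))
    y <- sample(round(rnorm(sample(2:8, 1)), 1))
    expect_equal(uStatistic(x, y)$U, bruteU(x, y))
  }
  # cross-check against the standard rank-sum test statistic
  set.seed(21)
  x <- rnorm(15); y <- rnorm(12)
  expect_equal(uStatistic(x, y)$U,
               unname(wilcox.test(x, y, exact = FALSE)$statistic))
  expect_error(uStatistic(numeric(0), 1:3), "nonempty")
})

test_that("feature ranking is correct, stable under ties, and monotone-invariant", {
  set.seed(22)
  n <- 30
  target <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[target, 3] <- x[target, 3] + 10  # perfectly separating
  r <- rankFeatures(x, target)
  expect_equal(r$name[1], "f3")
  expect_equal(r$score[1], (n / 2)^2)
  # exhaustive oracle: sort by brute-force scores
  brute <- vapply(1:5, function(j) {
    u <- bruteU(x[target, j], x[!target, j])
    max(u, (n / 2)^2 - u)
  }, numeric(1))
  expect_equal(r$name, paste0("f", order(-brute)))
  # identical copies keep original order (stable ties)
  xx <- x[, c(3, 3, 3)]
  colnames(xx) <- c("a", "b", "c")
  expect_equal(rankFeatures(xx, target)$name, c("a", "b", "c"))
  # invariance under strictly monotone transforms
  x2 <- x
  x2[, 3] <- exp(x2[, 3] / 5)
  x2[, 1] <- atan(x2[, 1])
  r2 <- rankFeatures(x2, target)
  expect_equal(r2$name, r$name)
  expect_equal(r2$score, r$score)
})

test_that("LDA matches MASS::lda predictions and the Fisher direction", {
  skip_if_not_installed("MASS")
  set.seed(23)
  d <- separableClasses(n_per = 40, g = 3, p = 4, sep = 1.2, seed = 23)
  fit <- fitLDA(d$x, d$y)
  ref <- MASS::lda(d$x, d$y)
  xnew <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, colnames(d$x)))
  agree <- mean(predict(fit, xnew) == predict(ref, xnew)$class)
  expect_gt(agree, 0.98)
  # 2-class equal-covariance Gaussians: boundary normal matches the
  # closed-form Fisher direction within 1 degree at n = 1e4
  set.seed(24)
  n <- 10000
  mu1 <- c(0, 0); mu2 <- c(1, 0.5)
  x <- rbind(matrix(rnorm(n), n / 2, 2),
             sweep(matrix(rnorm(n), n / 2, 2), 2, mu2, "+"))
  y <- rep(c("a", "b"), each = n / 2)
  fit2 <- fitLDA(x, y)
  w <- fit2$B[, 2] - fit2$B[, 1]
  # closed-form Fisher direction from the empirical class means and pooled
  # covariance (independent of the discriminant code path)
  m1 <- colMeans(x[y == "a", ]); m2 <- colMeans(x[y == "b", ])
  xc <- rbind(sweep(x[y == "a", ], 2, m1), sweep(x[y == "b", ], 2, m2))
  Sp <- crossprod(xc) / (n - 2)
  fisher <- solve(Sp, m2 - m1)
  angle <- acos(sum(w * fisher) / sqrt(sum(w^2) * sum(fisher^2))) * 180 / pi
  expect_lt(angle, 1)
})

test_that("SFS accepts only strict improvements and respects initialization", {
  set.seed(25)
  n <- 40
  target <- rep(c(TRUE, FALSE), each = n / 2)
  # single feature: accepted by initialization
  x1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "only"))
  expect_equal(sfsOneVsRest(x1, target)$accepted, "only")
  # duplicated column can never strictly improve
  inf <- rnorm(n) + ifelse(target, 3, 0)
  x2 <- cbind(a = inf, b = inf, c = rnorm(n))
  res <- sfsOneVsRest(x2, target)
  expect_false(all(c("a", "b") %in% res$accepted))
  # the greedy trace is strictly increasing
  expect_true(all(diff(res$trace) > 0) || length(res$trace) == 1)
})

test_that("SFS finds the exhaustive optimum on nested informative designs", {
  # orthogonal informative dimensions with decreasing strength + pure noise:
  # the greedy path and the exhaustive best subset coincide by construction
  set.seed(26)
  n <- 40
  target <- rep(c(TRUE, FALSE), each = n / 2)
  x <- cbind(
    f1 = rnorm(n) * 0.7 + ifelse(target, 4, 0),
    f2 = rnorm(n) * 0.7 + ifelse(target, 3, 0),
    f3 = rnorm(n) * 0.7 + ifelse(target, 2, 0),
    n1 = rnorm(n),
    n2 = rnorm(n)
  )
  res <- sfsOneVsRest(x, target)
  yb <- factor(ifelse(target, "t", "r"))
  subsets <- unlist(lapply(1:5, function(k)
    combn(colnames(x), k, simplify = FALSE)), recursive = FALSE)
  exhaustive <- vapply(subsets, function(s)
    loocvAccuracyLDA(x[, s, drop = FALSE], yb), numeric(1))
  expect_equal(res$finalAccuracy, max(exhaustive))
  # final accuracy never below the top-1 feature alone
  top1 <- loocvAccuracyLDA(x[, res$ranked$name[1], drop = FALSE], yb)
  expect_gte(res$finalAccuracy, top1)
})

test_that("merge-and-reselect covers all class signals", {
  # three classes, each separated from the rest by its own private feature
  set.seed(27)
  n_per <- 20
  y <- factor(rep(c("a", "b", "c"), each = n_per))
  x <- cbind(
    fa = rnorm(3 * n_per, 0, 0.5) + ifelse(y == "a", 4, 0),
    fb = rnorm(3 * n_per, 0, 0.5) + ifelse(y == "b", 4, 0),
    fc = rnorm(3 * n_per, 0, 0.5) + ifelse(y == "c", 4, 0),
    noise = rnorm(3 * n_per)
  )
  sel <- selectFeaturesSFS(x, y)
  expect_true(all(c("fa", "fb", "fc") %in% sel$selected) ||
                sum(c("fa", "fb", "fc") %in% sel$selected) >= 2)
  # multiclass LOOCV with the final set must reach near-perfect accuracy here
  expect_gt(sel$merge$finalAccuracy, 0.9)
  # identical candidate sets: final is a subset of that set
  m <- mergeAndReselect(list(c("fa", "fb"), c("fa", "fb")), x, y,
                        setNames(c(4, 3, 2, 1), colnames(x)))
  expect_true(all(m$selected %in% c("fa", "fb")))
  # union of size one returns that feature
  m1 <- mergeAndReselect(list("fa", "fa"), x, y,
                         setNames(c(4, 3, 2, 1), colnames(x)))
  expect_equal(m1$selected, "fa")
})

test_that("selection does not inflate under label permutation", {
  set.seed(28)
  n <- 24
  informative <- cbind(
    f1 = rnorm(n) + rep(c(3, 0), each = n / 2),
    f2 = rnorm(n) + rep(c(0, 3), each = n / 2),
    f3 = rnorm(n), f4 = rnorm(n)
  )
  y <- rep(c(TRUE, FALSE), each = n / 2)
  sizes <- function(permute) {
    vapply(1:50, function(i) {
      set.seed(100 + i)
      yy <- if (permute) sample(y) else y
      length(sfsOneVsRest(informative, yy)$accepted)
    }, numeric(1))
  }
  expect_lte(median(sizes(TRUE)), median(sizes(FALSE)))
})

test_that("PCA reduction projects with training statistics only", {
  # data exactly on a line: one component reconstructs perfectly
  set.seed(29)
  s <- rnorm(30)
  x <- cbind(s, 2 * s, -s)
  red <- pcaReduce(x, x, 1)
  expect_equal(ncol(red$train), 1)
  expect_equal(abs(red$train[, 1]), sqrt(6) * abs(s - mean(s)), tolerance = 1e-8)
  # full-rank rotation preserves pairwise distances
  x2 <- matrix(rnorm(40 * 3), 40, 3)
  red2 <- pcaReduce(x2[1:30, ], x2[31:40, ], 3)
  expect_equal(as.matrix(dist(red2$train)), as.matrix(dist(x2[1:30, ])),
               ignore_attr = TRUE, tolerance = 1e-9)
  # requesting more components than the rank degrades gracefully
  expect_message(red3 <- pcaReduce(x, x, 3), "rank")
  expect_lte(red3$nComponents, 2)
  # test rows are centered with training means
  xtr <- matrix(rnorm(20 * 2), 20, 2)
  xte <- matrix(rnorm(6 * 2, mean = 5), 6, 2)
  red4 <- pcaReduce(xtr, xte, 2)
  pr <- prcomp(xtr)
  expect_equal(red4$test, sweep(xte, 2, colMeans(xtr)) %*% pr$rotation[, 1:2],
               ignore_attr = TRUE)
})
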