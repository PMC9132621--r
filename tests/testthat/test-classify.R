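test_that("classifier specs reproduce the reference defaults verbatim", {
  expect_equal(classifierSpec("knn")$params,
               list(k = 70L, distance = "correlation",
                    weight = "squared-inverse"))
  expect_equal(classifierSpec("ld")$params, list(gamma = 0))
  expect_equal(classifierSpec("svm")$params,
               list(boxConstraint = 3, kernelScale = 5.6))
  expect_equal(classifierSpec("dt")$params,
               list(maxSplits = 51L, split = "deviance"))
  expect_error(classifierSpec("knn", bogus = 1), "unknown hyperparameters")
})

test_that("train/predict behaves on canonical geometries", {
  set.seed(51)
  # 1-NN on its own training points: zero training error
  X <- matrix(runif(40 * 3), 40)
  y <- factor(rep(c("a", "b"), 20))
  pr <- trainPredict(classifierSpec("knn", k = 1, distance = "euclidean",
                                    weight = "none"), X, y, X)
  expect_equal(as.character(pr$labels), as.character(y))
  # widely separated blobs: SVM at the default spec classifies perfectly
  Xb <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
              matrix(rnorm(60, 4, 0.2), ncol = 2))
  yb <- factor(rep(c("a", "b"), each = 30))
  cvb <- crossValidate(classifierSpec("svm"), Xb, yb, folds = 5, seed = 1)
  expect_equal(cvb@pooledError, 0)
  expect_error(trainPredict(classifierSpec("nb"), X, factor(rep("a", 40)), X),
               "both classes")
})

test_that("naive Bayes approaches the analytic Bayes error", {
  # univariate equal-prior normals N(0,1) vs N(2,1): Bayes error = pnorm(-1)
  set.seed(52)
  n <- 2000
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- c(rnorm(n / 2, 0, 1), rnorm(n / 2, 2, 1))
  cv <- crossValidate(classifierSpec("nb"), cbind(x), y, folds = 5, seed = 2)
  expect_lt(abs(cv@pooledError - pnorm(-1)), 0.03)
})

test_that("manual LD and NB agree with the reference library fits", {
  set.seed(53)
  n <- 120
  X <- rbind(matrix(rnorm(n, 0, 1), ncol = 2),
             matrix(rnorm(n, 1.5, 1), ncol = 2))
  y <- factor(rep(c("a", "b"), each = n / 2))
  Xte <- X + matrix(rnorm(2 * n, 0, 0.05), ncol = 2)
  ld <- trainPredict(classifierSpec("ld"), X, y, Xte)
  ref <- predict(MASS::lda(X, grouping = y), Xte)
  expect_gte(mean(as.character(ld$labels) == as.character(ref$class)), 0.99)
  expect_equal(ld$scores, unname(ref$posterior[, 2]), tolerance = 1e-6)
  nb <- trainPredict(classifierSpec("nb"), X, y, Xte)
  refnb <- predict(e1071::naiveBayes(X, y), Xte, type = "raw")
  expect_equal(nb$scores, unname(refnb[, 2]), tolerance = 1e-4)
})

test_that("LD falls back to a ridge with a warning when covariance is singular", {
  set.seed(54)
  X <- matrix(rnorm(20 * 50), 20)       # p > n: singular pooled covariance
  y <- factor(rep(c("a", "b"), 10))
  expect_warning(trainPredict(classifierSpec("ld"), X, y, X), "ridge")
})

test_that("decision tree honors the maximum-splits cap", {
  set.seed(55)
  X <- matrix(runif(200 * 2), 200)
  y <- factor(ifelse(X[, 1] + 0.3 * sin(9 * X[, 2]) +
                       rnorm(200, 0, 0.12) > 0.5, "a", "b"))
  pr1 <- trainPredict(classifierSpec("dt", maxSplits = 1L), X, y, X)
  # a single split yields at most two distinct leaf scores
  expect_lte(length(unique(pr1$scores)), 2L)
  prBig <- trainPredict(classifierSpec("dt", maxSplits = 51L), X, y, X)
  expect_gt(length(unique(prBig$scores)), 2L)
})

test_that("cross-validation is stratified, exhaustive and seeded", {
  set.seed(56)
  X <- matrix(runif(83 * 4), 83)
  y <- factor(c(rep("a", 43), rep("b", 40)))
  cv <- crossValidate(classifierSpec("nb"), X, y, folds = 10, seed = 4)
  # every observation predicted exactly once
  expect_equal(sort(cv@predictions$row), 1:83)
  # fold sizes differ by at most one
  expect_lte(diff(range(table(cv@foldAssignments))), 1)
  # determinism
  cv2 <- crossValidate(classifierSpec("nb"), X, y, folds = 10, seed = 4)
  expect_identical(cv@predictions, cv2@predictions)
  # permuted-label null: error near chance over seeds
  errs <- vapply(1:20, function(s) {
    set.seed(400 + s)
    Xn <- matrix(runif(100 * 3), 100)
    yn <- factor(rep(c("a", "b"), 50))
    crossValidate(classifierSpec("knn", k = 1, distance = "euclidean",
                                 weight = "none"),
                  Xn, yn, folds = 5, seed = s)@pooledError
  }, 0)
  expect_lt(abs(mean(errs) - 0.5), 0.08)
  # twins: when every point keeps a coordinate-identical same-class twin in
  # each training fold (true under this seed's assignment), 1-NN is perfect
  base <- matrix(runif(20 * 2), 20)
  Xt <- rbind(base, base, base)
  yt <- factor(rep(rep(c("a", "b"), 10), 3))
  cvt <- crossValidate(classifierSpec("knn", k = 1, distance = "euclidean",
                                      weight = "none"),
                       Xt, yt, folds = 3, seed = 7)
  fa <- cvt@foldAssignments
  expect_true(all(vapply(1:20, function(i)
    length(unique(fa[c(i, i + 20, i + 40)])) > 1, TRUE)))
  expect_equal(cvt@pooledError, 0)
})

test_that("Bayesian tuning exhausts finite spaces and matches a grid oracle", {
  set.seed(57)
  d <- makeInformative(90, 4, 2, sd = 0.45, seed = 57)
  space <- list(k = list(type = "int", lo = 1, hi = 20),
                distance = list(type = "cat", values = "euclidean"))
  # budget = cardinality: every configuration evaluated, incumbent = grid min
  tt <- bayesTune("knn", d$X, d$y, budget = 20, seed = 3, folds = 5,
                  searchSpace = space)
  expect_equal(nrow(tt@iterations), 20L)
  gridErr <- vapply(1:20, function(kk)
    crossValidate(classifierSpec("knn", k = kk, distance = "euclidean",
                                 weight = "squared-inverse"),
                  d$X, d$y, folds = 5, seed = 3 + 104729L)@pooledError, 0)
  expect_equal(tt@best$error, min(gridErr))
  expect_equal(tt@best$spec$params$k, which.min(gridErr))
  # below-cardinality budget: the surrogate lands within one step of the
  # exhaustive minimum of the (near-convex in k) error surface
  tt2 <- bayesTune("knn", d$X, d$y, budget = 12, seed = 3, folds = 5,
                   searchSpace = space)
  expect_lte(abs(tt2@best$spec$params$k - which.min(gridErr)), 1L)
  expect_lte(tt2@best$error, gridErr[1] + 1e-12)
  # identical seeds give identical traces
  tt3 <- bayesTune("knn", d$X, d$y, budget = 12, seed = 3, folds = 5,
                   searchSpace = space)
  expect_identical(tt2@iterations, tt3@iterations)
  expect_error(bayesTune("knn", d$X, d$y, budget = 3), "budget")
})

test_that("tuning with seeded defaults never loses to the default spec", {
  set.seed(58)
  d <- makeInformative(80, 6, 2, sd = 0.4, seed = 58)
  for (fam in c("svm", "nb", "ld")) {
    tt <- bayesTune(fam, d$X, d$y, budget = 8, seed = 5, folds = 5)
    defErr <- suppressWarnings(
      crossValidate(classifierSpec(fam), d$X, d$y, folds = 5,
                    seed = 5 + 104729L)@pooledError)
    expect_lte(tt@best$error, defErr + 1e-12, label = fam)
  }
})
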