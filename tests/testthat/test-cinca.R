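test_that("chi-square scores match the brute-force contingency oracle", {
  # hand-computable case: binary feature perfectly matching balanced labels
  y40 <- factor(rep(c("a", "b"), each = 20))
  x40 <- as.numeric(y40 == "b")
  r <- chi2Scores(cbind(x40), y40)
  expect_equal(r$scores, 40)
  # constant feature carries no association
  expect_equal(chi2Scores(cbind(rep(2, 40)), y40)$scores, 0)
  # exhaustive small instances against the explicit-contingency oracle
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    nb <- sample(2:5, 1)
    y <- factor(sample(c("a", "b"), n, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) next
    X <- cbind(runif(n), rnorm(n), rep(1, n),
               sample(0:2, n, replace = TRUE))
    r <- chi2Scores(X, y, nBins = nb)
    for (j in 1:4)
      expect_equal(r$scores[j], chi2Oracle(X[, j], y, nb),
                   tolerance = 1e-10, label = sprintf("rep %d col %d", rep, j))
  }
  expect_error(chi2Scores(cbind(runif(8)), rep("a", 8)), "two classes")
})

test_that("null chi-square statistics follow the chi-square reference law", {
  # independent features and labels: the statistic is approximately
  # chi-square with (bins - 1) degrees of freedom
  set.seed(22)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(runif(n * 1000), n)
  r <- chi2Scores(X, y, nBins = 10L)
  tail95 <- mean(r$scores > qchisq(0.95, df = 9))
  expect_gt(tail95, 0.03)
  expect_lt(tail95, 0.07)
})

test_that("top-k filtering preserves order and breaks ties by index", {
  r <- list(scores = c(3, 5, 5, 1), order = order(-c(3, 5, 5, 1), 1:4))
  expect_equal(selectTopK(r, 4), c(2L, 3L, 1L, 4L))   # tie: 2 before 3
  expect_equal(selectTopK(r, 2), c(2L, 3L))
  expect_error(selectTopK(r, 5), "exceeds")
  wide <- makeInformative(12, 1200, 1, seed = 4)
  expect_length(selectTopK(chi2Scores(wide$X, wide$y)), 1000L)
})

test_that("NCA weights recover informative features and respect symmetry", {
  # an informative feature must out-weigh pure noise across data seeds
  for (s in 1:10) {
    d <- makeInformative(60, 6, 1, sd = 0.25, seed = s)
    Xs <- apply(d$X, 2, function(v) (v - min(v)) / diff(range(v)))
    w <- ncaWeights(Xs, d$y, seed = 1)$w
    expect_equal(which.max(w), 1L, label = sprintf("seed %d", s))
  }
  # duplicated columns receive near-equal weights
  d <- makeInformative(50, 4, 1, seed = 99)
  Xs <- apply(d$X, 2, function(v) (v - min(v)) / diff(range(v)))
  Xdup <- cbind(Xs, Xs[, 1])
  w <- ncaWeights(Xdup, d$y, seed = 1)$w
  expect_lt(abs(w[1] - w[5]) / max(w[1], w[5]), 0.05)
  # heavy regularization shrinks weights toward zero
  wBig <- ncaWeights(Xs, d$y, lambda = 1e4, seed = 1)$w
  wSmall <- ncaWeights(Xs, d$y, lambda = 1 / 50, seed = 1)$w
  expect_lt(max(wBig), 0.05 * max(wSmall))
  expect_error(ncaWeights(cbind(c(1, NA, 3, 4)), factor(c(1, 2, 1, 2))),
               "finite")
})

test_that("1-NN cross-validated error behaves on twins, nulls and XOR", {
  # identical-coordinate same-class twins: the nearest neighbor is the twin
  set.seed(23)
  base <- matrix(runif(30 * 3), 30)
  yb <- factor(rep(c("a", "b"), 15))
  X <- rbind(base, base, base)
  y <- factor(rep(yb, 3))
  expect_equal(knnCvError(X, y, k = 1, folds = 3, seed = 5), 0)
  # permuted labels: error centers on chance
  errs <- vapply(1:20, function(s) {
    set.seed(s + 100)
    Xn <- matrix(runif(200 * 5), 200)
    yn <- factor(rep(c("a", "b"), each = 100))
    knnCvError(Xn, yn, k = 1, folds = 10, seed = s)
  }, 0)
  expect_lt(abs(mean(errs) - 0.5), 0.08)
  # 4-point XOR split so each held-out point's nearest is the other class
  Xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  yx <- factor(c("a", "a", "b", "b"))
  # folds {1,3} vs {2,4}: every test point's nearest training point differs
  # in class (distance 1 beats distance sqrt(2))
  expect_equal(knnCvError(Xx, yx, k = 1, folds = 2, seed = 1), 1.0)
  expect_error(knnCvError(Xx, yx, k = 5, folds = 2, seed = 1),
               "smaller than")
})

test_that("INCA returns the argmin of its own curve and recovers signal", {
  d <- makeInformative(40, 30, 2, sd = 0.2, seed = 7)
  Xs <- apply(d$X, 2, function(v) (v - min(v)) / diff(range(v)))
  w <- ncaWeights(Xs, d$y, seed = 1)$w
  sel <- incaSelect(Xs, d$y, w, rangeLo = 2, rangeHi = 30, folds = 5,
                    seed = 3)
  expect_equal(sel$minError, min(sel$errorCurve))
  expect_equal(length(sel$errorCurve), 29L)
  expect_equal(sel$selected, sel$order[seq_len(sel$lStar)])
  # degenerate range: single candidate
  s1 <- incaSelect(Xs, d$y, w, rangeLo = 5, rangeHi = 5, folds = 5, seed = 3)
  expect_length(s1$errorCurve, 1L)
  expect_equal(s1$lStar, 5L)
  # clamping
  expect_message(incaSelect(Xs, d$y, w, rangeLo = 2, rangeHi = 500,
                            folds = 5, seed = 3), "clamping")
  # informative-plus-noise recovery across seeds: error no worse at the
  # informative prefix than at the full width, and signal columns selected
  for (s in 1:5) {
    d2 <- makeInformative(60, 200, 5, sd = 0.25, seed = 200 + s)
    Xs2 <- apply(d2$X, 2, function(v) (v - min(v)) / diff(range(v)))
    w2 <- ncaWeights(Xs2, d2$y, seed = 1)$w
    sel2 <- incaSelect(Xs2, d2$y, w2, rangeLo = 5, rangeHi = 200,
                       folds = 5, seed = 3)
    expect_lte(sel2$errorCurve[1], sel2$errorCurve[length(sel2$errorCurve)])
    expect_true(all(1:5 %in% sel2$selected),
                label = sprintf("informative set recovered, seed %d", s))
  }
})

test_that("the composed selector is deterministic and maps to global indices", {
  d <- makeInformative(40, 1500, 3, sd = 0.25, seed = 31)
  sr1 <- cinca(d$X, d$y, chiK = 300, rangeLo = 3, rangeHi = 60, folds = 5,
               seed = 9)
  sr2 <- cinca(d$X, d$y, chiK = 300, rangeLo = 3, rangeHi = 60, folds = 5,
               seed = 9)
  expect_identical(selectedFeatures(sr1), selectedFeatures(sr2))
  expect_identical(errorCurve(sr1), errorCurve(sr2))
  expect_length(sr1@chiOrder, 300L)
  expect_true(all(1:3 %in% selectedFeatures(sr1)))
  expect_equal(sr1@minError, min(errorCurve(sr1)))
  expect_s4_class(sr1, "SelectionResult")
})

test_that("whole-data selection is optimistic on noise; fold-internal is not", {
  # pure-noise features: any apparent signal is selection leakage
  set.seed(41)
  X <- matrix(runif(60 * 400), 60)
  y <- factor(rep(c("a", "b"), each = 30))
  sr <- cinca(X, y, chiK = 400, rangeLo = 20, rangeHi = 120, folds = 5,
              seed = 2, scope = "fold")
  # the in-search curve minimum looks far better than chance ...
  expect_lt(sr@minError, 0.35)
  # ... but honest held-out error stays at chance
  expect_gt(sr@heldOutError, 0.4)
  expect_lt(sr@heldOutError, 0.6)
  expect_equal(sr@scope, "fold")
})
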