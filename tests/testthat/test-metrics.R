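test_that("confusion counts are exact and symmetric in the positive class", {
  yt <- c(rep("pos", 6), rep("neg", 4))
  cm <- confusionCounts(yt, yt, positive = "pos")
  expect_equal(cm[c("tp", "tn", "fp", "fn")],
               list(tp = 6L, tn = 4L, fp = 0L, fn = 0L))
  allPos <- confusionCounts(yt, rep("pos", 10), positive = "pos")
  expect_equal(allPos[c("tp", "tn", "fp", "fn")],
               list(tp = 6L, tn = 0L, fp = 4L, fn = 0L))
  # swapping the positive convention transposes the table
  set.seed(61)
  yr <- sample(c("a", "b"), 50, replace = TRUE)
  pr <- sample(c("a", "b"), 50, replace = TRUE)
  ca <- confusionCounts(yr, pr, positive = "a")
  cb <- confusionCounts(yr, pr, positive = "b")
  expect_equal(ca$tp, cb$tn)
  expect_equal(ca$fp, cb$fn)
  expect_error(confusionCounts(yr, rep("c", 50)), "outside")
  expect_error(confusionCounts(yr, pr[1:10]), "equal length")
})

test_that("scalar metrics reproduce the defining formulas exactly", {
  # direct-formula oracle over random count vectors
  set.seed(62)
  for (i in 1:1000) {
    cm <- as.list(setNames(sample(0:50, 4, replace = TRUE),
                           c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cm)) == 0) next
    m <- suppressWarnings(summarizeConfusion(cm))
    tot <- cm$tp + cm$tn + cm$fp + cm$fn
    expect_equal(m[["accuracy"]], 100 * (cm$tp + cm$tn) / tot, tolerance = 1e-12)
    if (cm$tp + cm$fp > 0)
      expect_equal(m[["precision"]], 100 * cm$tp / (cm$tp + cm$fp), tolerance = 1e-12)
    if (cm$tp + cm$fn > 0)
      expect_equal(m[["recall"]], 100 * cm$tp / (cm$tp + cm$fn), tolerance = 1e-12)
    p <- m[["precision"]] / 100; r <- m[["recall"]] / 100
    if (p + r > 0)
      expect_equal(m[["f1"]], 100 * 2 * p * r / (p + r), tolerance = 1e-12)
  }
  # symmetric case
  ms <- summarizeConfusion(list(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(unname(ms), rep(50, 4))
  # degenerate all-positive truth
  md <- summarizeConfusion(list(tp = 1, tn = 0, fp = 0, fn = 0))
  expect_equal(md[["accuracy"]], 100)
  expect_equal(md[["recall"]], 100)
  w <- capture_warnings(summarizeConfusion(list(tp = 0, tn = 5, fp = 0,
                                                fn = 0)))
  expect_length(w, 3L)                     # precision, recall, F1 all guard
  expect_match(w, "zero denominator", all = TRUE)
  expect_error(summarizeConfusion(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "empty")
})

test_that("the published precision/recall pair gives the published F1", {
  expect_equal(round(f1Score(99.11, 99.12), 2), 99.11)
  expect_equal(round(f1Score(98.54, 98.53), 2), 98.53)
  expect_equal(f1Score(0, 0), 0)
})

test_that("AUC equals the Mann-Whitney rank statistic", {
  set.seed(63)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    y <- c(rep("x", 5), rep("z", 5),
           sample(c("x", "z"), n - 10, replace = TRUE))
    s <- round(rnorm(n), sample(0:1, 1))  # coarse rounding forces ties
    r <- rocAuc(y, s, positive = "z")
    expect_equal(r$auc, aucOracle(y, s, "z"), tolerance = 1e-12,
                 label = sprintf("instance %d", i))
  }
  # perfect scores
  yy <- rep(c("n", "p"), each = 10)
  expect_equal(rocAuc(yy, as.numeric(yy == "p"), positive = "p")$auc, 1.0)
  # label-independent scores: chance-level area
  set.seed(64)
  yn <- sample(c("n", "p"), 2000, replace = TRUE)
  sn <- rnorm(2000)
  expect_lt(abs(rocAuc(yn, sn, positive = "p")$auc - 0.5), 0.03)
  expect_error(rocAuc(rep("p", 5), rnorm(5)), "both classes")
  expect_error(rocAuc(yy, c(rnorm(19), NA)), "finite")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(65)
  y <- sample(c("n", "p"), 100, replace = TRUE)
  s <- rnorm(100)
  a0 <- rocAuc(y, s, positive = "p")$auc
  for (f in list(function(x) 3 * x + 2, function(x) exp(x),
                 function(x) atan(x)))
    expect_equal(rocAuc(y, f(s), positive = "p")$auc, a0, tolerance = 1e-12)
})

test_that("evaluation reports are internally consistent", {
  set.seed(66)
  d <- makeInformative(80, 3, 1, sd = 0.5, seed = 66)
  cv <- crossValidate(classifierSpec("nb"), d$X, d$y, folds = 5, seed = 2)
  rep <- evalReport(cv, positive = "b")
  m <- reportMetrics(rep)
  expect_true(all(m >= 0 & m <= 100))
  expect_equal(m[["f1"]], f1Score(m[["precision"]], m[["recall"]]),
               tolerance = 1e-12)
  cm <- rep@confusion
  expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 80)
  expect_equal(m[["accuracy"]],
               100 * mean(cv@predictions$truth == cv@predictions$predicted))
  expect_true(rep@auc >= 0 && rep@auc <= 1)
  # per-fold accuracies pool back to the headline accuracy
  expect_equal(mean(rep@foldAccuracy), m[["accuracy"]] / 100,
               tolerance = 0.01)
  # macro metrics average the two per-class rows
  expect_equal(unname(rep@macro), unname(colMeans(rep@perClass)))
})
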