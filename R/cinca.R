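#' Chi-square ranking of continuous features
#'
#' Each feature is discretized into `nBins` equal-width bins over its
#' observed range (constant features score 0) and the Pearson chi-square
#' statistic of the bin-by-class contingency table is computed; cells with
#' zero expected count contribute nothing. Ties in the descending-score
#' ranking break by ascending feature index.
#'
#' @param X numeric matrix, observations in rows.
#' @param y binary class labels (factor or coercible).
#' @param nBins number of equal-width bins (default 10).
#' @return list with `scores` (one non-negative statistic per feature) and
#'   `order` (feature indices by descending score).
#' @export
chi2Scores <- function(X, y, nBins = 10L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  y <- as.factor(y)
  if (nlevels(y) < 2L)
    stop("labels must contain at least two classes", call. = FALSE)
  nBins <- .assertScalarCount(nBins, "nBins", lo = 2L)
  n <- nrow(X); p <- ncol(X)
  lo <- X[1L, ]; hi <- X[1L, ]
  for (i in seq_len(n)[-1L]) {
    lo <- pmin(lo, X[i, ])
    hi <- pmax(hi, X[i, ])
  }
  span <- hi - lo
  const <- span <= 0
  span[const] <- 1
  U <- sweep(sweep(X, 2L, lo, "-"), 2L, span, "/")
  B <- pmin(floor(U * nBins) + 1L, nBins)         # n x p bin ids
  classes <- levels(y)
  colBase <- rep((seq_len(p) - 1L) * nBins, each = n)
  counts <- lapply(classes, function(cl) {
    rows <- y == cl
    idx <- colBase[rows] + B[rows, , drop = FALSE]
    t(matrix(tabulate(idx, nbins = nBins * p), nBins, p))
  })                                              # each p x nBins
  nk <- as.numeric(table(y))
  rowTot <- Reduce(`+`, counts)                   # p x nBins
  chi <- numeric(p)
  for (k in seq_along(classes)) {
    E <- rowTot * (nk[k] / n)
    O <- counts[[k]]
    term <- (O - E)^2 / E
    term[E == 0] <- 0
    chi <- chi + rowSums(term)
  }
  chi[const] <- 0
  list(scores = chi, order = order(-chi, seq_len(p)))
}

#' Keep the top-k ranked features
#'
#' @param ranking output of [chi2Scores()].
#' @param k number of features to keep (default 1000).
#' @return integer vector: first `k` entries of the ranking, order preserved.
#' @export
selectTopK <- function(ranking, k = 1000L) {
  k <- .assertScalarCount(k, "k")
  if (k > length(ranking$order))
    stop(sprintf("k (%d) exceeds the number of features (%d)",
                 k, length(ranking$order)), call. = FALSE)
  ranking$order[seq_len(k)]
}

#' Neighborhood component analysis feature weights
#'
#' Maximizes the soft leave-one-out nearest-neighbor objective
#' \deqn{\sum_i p_i - \lambda \sum_r w_r^2,\qquad
#'   p_{ij} \propto \exp(-\sum_r w_r^2 |x_{ir} - x_{jr}|),\ p_{ii} = 0,}
#' where \eqn{p_i} sums \eqn{p_{ij}} over same-class neighbors, by gradient
#' ascent with backtracking step halving. Features are expected min-max
#' scaled to `[0, 1]` per column. Weights start equal, scaled so the mean
#' weighted pairwise distance is 1 (a unit-weight start collapses the
#' softmax for wide matrices; see the methods vignette).
#'
#' @param X numeric matrix (observations x features), min-max scaled.
#' @param y binary labels.
#' @param lambda ridge penalty on the squared weights; default `1/nrow(X)`.
#' @param seed RNG seed (the optimizer itself is deterministic; the seed is
#'   recorded for provenance).
#' @param maxIter,tol gradient-ascent budget and relative objective tolerance.
#' @return list with `w` (non-negative weights), `objective` trace, `lambda`,
#'   `converged`, `seed`.
#' @export
ncaWeights <- function(X, y, lambda = NULL, seed = 1L, maxIter = 200L,
                       tol = 1e-6) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  y <- as.factor(y)
  if (is.null(lambda)) lambda <- 1 / n
  same <- outer(y, y, `==`)
  diag(same) <- FALSE
  ii <- rep(seq_len(n), times = n)    # pair (i, j): i fastest, column-major
  jj <- rep(seq_len(n), each = n)
  A <- abs(X[ii, , drop = FALSE] - X[jj, , drop = FALSE])   # n^2 x p
  evalObj <- function(w) {
    d <- as.vector(A %*% (w^2))
    D <- matrix(d, n, n)
    K <- exp(-D)
    diag(K) <- 0
    Z <- rowSums(K)
    Z[Z <= 0] <- .Machine$double.xmin
    P <- K / Z
    pi <- rowSums(P * same)
    obj <- sum(pi) - lambda * sum(w^2)
    list(obj = obj, P = P, pi = pi)
  }
  grad <- function(w, st) {
    Cf <- st$P * st$pi - st$P * same    # coefficient per ordered pair (i, j)
    g <- as.vector(crossprod(A, as.vector(Cf)))
    2 * w * g - 2 * lambda * w
  }
  meanD <- mean(A %*% rep(1, p))
  w <- rep(1 / sqrt(max(meanD, .Machine$double.eps)), p)
  st <- evalObj(w)
  objTrace <- st$obj
  step <- 1
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    g <- grad(w, st)
    accepted <- FALSE
    for (h in seq_len(30L)) {
      wNew <- w + step * g
      stNew <- evalObj(wNew)
      if (stNew$obj >= st$obj) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    rel <- abs(stNew$obj - st$obj) / max(abs(st$obj), 1e-12)
    w <- wNew; st <- stNew
    objTrace <- c(objTrace, st$obj)
    step <- step * 1.2
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("NCA gradient ascent hit the iteration cap; returning best iterate",
            call. = FALSE)
  list(w = abs(w), objective = objTrace, lambda = lambda,
       converged = converged, seed = as.integer(seed))
}

# k-NN prediction from a test x train distance matrix (smallest distance
# wins ties via order()'s stable first occurrence).
.knnFromDist <- function(Dte, yTrain, k) {
  yTrain <- as.factor(yTrain)
  n <- ncol(Dte)
  k <- min(k, n)
  lev <- levels(yTrain)
  pred <- character(nrow(Dte))
  score <- numeric(nrow(Dte))
  for (i in seq_len(nrow(Dte))) {
    o <- order(Dte[i, ])[seq_len(k)]
    votes <- table(factor(yTrain[o], levels = lev))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # tie: the class whose voters are nearer wins
      md <- vapply(lev[top], function(cl)
        mean(Dte[i, o[yTrain[o] == cl]]), 0)
      top <- top[which.min(md)]
    }
    pred[i] <- lev[top[1L]]
    score[i] <- votes[length(lev)] / k      # share voting the last level
  }
  list(labels = factor(pred, levels = lev), score = score)
}

#' Cross-validated k-nearest-neighbor misclassification rate
#'
#' Stratified seeded fold assignment, Euclidean k-NN prediction of each
#' held-out fold, pooled error = misclassified / n. This is the error
#' functional the iterative selector minimizes (defaults: k = 1, 10 folds).
#'
#' @param X numeric matrix (observations x features).
#' @param y binary labels.
#' @param k neighbors (default 1).
#' @param folds folds (default 10).
#' @param seed fold-assignment seed.
#' @return pooled misclassification rate in `[0, 1]`.
#' @export
knnCvError <- function(X, y, k = 1L, folds = 10L, seed = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.factor(y)
  fold <- .stratifiedFolds(y, folds, seed)
  k <- .assertScalarCount(k, "k")
  if (k >= length(y) - max(table(fold)))
    stop("k must be smaller than the smallest training fold", call. = FALSE)
  D2 <- .pairwiseSqEuclidean(X)
  err <- 0L
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    if (!length(te)) next
    tr <- which(fold != f)
    pr <- .knnFromDist(D2[te, tr, drop = FALSE], y[tr], k)
    err <- err + sum(pr$labels != y[te])
  }
  err / length(y)
}

.pairwiseSqEuclidean <- function(X) {
  G <- tcrossprod(X)
  s <- diag(G)
  D2 <- outer(s, s, `+`) - 2 * G
  D2[D2 < 0] <- 0
  D2
}

#' Iterative NCA prefix selection
#'
#' Sorts features by descending NCA weight (ties by ascending index) and,
#' for every prefix length in `[rangeLo, rangeHi]`, computes the
#' cross-validated k-NN misclassification on the prefix columns; returns the
#' smallest prefix attaining the minimum. Squared Euclidean distances are
#' accumulated incrementally over the weight-ordered columns, so the whole
#' sweep costs one pass over the features.
#'
#' @param X numeric matrix (observations x features), typically min-max
#'   scaled survivor columns of the chi-square stage.
#' @param y binary labels.
#' @param weights NCA weight per column of `X`.
#' @param rangeLo,rangeHi prefix-size sweep bounds (defaults 100, 1000);
#'   `rangeHi` is clamped to `ncol(X)` with a message.
#' @param folds,seed,k cross-validation settings of the error functional.
#' @return list with `selected` (column indices of `X`, weight order),
#'   `lStar`, `errorCurve` (named by prefix size), `minError`, `order`.
#' @export
incaSelect <- function(X, y, weights, rangeLo = 100L, rangeHi = 1000L,
                       folds = 10L, seed = 1L, k = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.factor(y)
  if (length(weights) != ncol(X))
    stop("one weight per feature column required", call. = FALSE)
  rangeLo <- .assertScalarCount(rangeLo, "rangeLo")
  rangeHi <- .assertScalarCount(rangeHi, "rangeHi")
  if (rangeLo > rangeHi)
    stop("rangeLo exceeds rangeHi", call. = FALSE)
  if (rangeHi > ncol(X)) {
    message(sprintf("clamping rangeHi from %d to the %d available features",
                    rangeHi, ncol(X)))
    rangeHi <- ncol(X)
    rangeLo <- min(rangeLo, rangeHi)
  }
  ord <- order(-weights, seq_along(weights))
  fold <- .stratifiedFolds(y, folds, seed)
  n <- nrow(X)
  foldIdx <- lapply(seq_len(folds), function(f)
    list(te = which(fold == f), tr = which(fold != f)))
  D2 <- matrix(0, n, n)
  ls <- rangeLo:rangeHi
  curve <- setNames(numeric(length(ls)), ls)
  for (l in seq_len(rangeHi)) {
    v <- X[, ord[l]]
    D2 <- D2 + (outer(v, v, `-`))^2
    if (l >= rangeLo) {
      err <- 0L
      for (fi in foldIdx) {
        if (!length(fi$te)) next
        if (k == 1L) {
          nn <- max.col(-D2[fi$te, fi$tr, drop = FALSE],
                        ties.method = "first")
          err <- err + sum(y[fi$tr][nn] != y[fi$te])
        } else {
          pr <- .knnFromDist(D2[fi$te, fi$tr, drop = FALSE], y[fi$tr], k)
          err <- err + sum(pr$labels != y[fi$te])
        }
      }
      curve[as.character(l)] <- err / n
    }
  }
  iStar <- which.min(curve)           # first minimum = smallest prefix
  lStar <- ls[iStar]
  list(selected = ord[seq_len(lStar)], lStar = lStar, errorCurve = curve,
       minError = unname(curve[iStar]), order = ord)
}

#' Two-stage chi-square + iterative-NCA feature selection
#'
#' The full hybrid selector: (1) chi-square ranking of all features,
#' (2) keep the top `chiK` (default 1000), (3) min-max scale the survivors
#' and learn NCA relevance weights, (4) sweep weight-ordered prefixes over
#' `[rangeLo, rangeHi]` and keep the prefix with the lowest cross-validated
#' k-NN misclassification. With `scope = "whole"` (the original procedure)
#' the selector sees all rows once; its error curve is then optimistically
#' biased for selection-level generalization claims. `scope = "fold"`
#' additionally refits the entire selector inside each outer fold and
#' reports the leakage-free pooled held-out 1-NN error in `heldOutError`
#' (the final reported selection is still the whole-data one, for
#' deployment).
#'
#' @param X numeric matrix (observations x features) or a
#'   `SummarizedExperiment` from [extractFeatures()] (assay `"features"`,
#'   features x images, with labels in `colData`).
#' @param y binary labels; taken from `colData(X)$label` when `X` is a
#'   `SummarizedExperiment`.
#' @param chiK chi-square survivor count (default 1000; clamped to the
#'   feature count).
#' @param nBins chi-square discretization bins.
#' @param rangeLo,rangeHi,folds,k prefix-sweep settings (see [incaSelect()]).
#' @param lambda NCA penalty (default `1/n`).
#' @param seed seed for fold assignments.
#' @param scope `"whole"` or `"fold"` (see Details).
#' @return a [SelectionResult-class]; `selected` holds indices into the
#'   original feature space.
#' @export
cinca <- function(X, y = NULL, chiK = 1000L, nBins = 10L, rangeLo = 100L,
                  rangeHi = 1000L, folds = 10L, k = 1L, lambda = NULL,
                  seed = 1L, scope = c("whole", "fold")) {
  scope <- match.arg(scope)
  prov <- data.frame()
  if (is(X, "SummarizedExperiment")) {
    if (is.null(y)) y <- colData(X)$label
    prov <- as.data.frame(rowData(X))
    X <- t(assay(X, "features"))
  }
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2L)
    stop("binary labels required", call. = FALSE)
  chiK <- min(.assertScalarCount(chiK, "chiK"), ncol(X))

  runOnce <- function(Xtr, ytr, foldSeed) {
    rk <- chi2Scores(Xtr, ytr, nBins)
    keep <- selectTopK(rk, chiK)
    fit <- .minMaxFit(Xtr[, keep, drop = FALSE])
    Xs <- .minMaxApply(Xtr[, keep, drop = FALSE], fit)
    nw <- ncaWeights(Xs, ytr, lambda = lambda, seed = foldSeed)
    sel <- incaSelect(Xs, ytr, nw$w, rangeLo = rangeLo, rangeHi = rangeHi,
                      folds = folds, seed = foldSeed, k = k)
    list(keep = keep, scaler = fit, weights = nw$w, sel = sel)
  }

  heldOut <- NA_real_
  if (scope == "fold") {
    fold <- .stratifiedFolds(y, folds, seed)
    wrong <- 0L
    for (f in seq_len(max(fold))) {
      te <- which(fold == f)
      tr <- which(fold != f)
      r <- runOnce(X[tr, , drop = FALSE], y[tr], foldSeed = seed + f)
      glob <- r$keep[r$sel$selected]
      scl <- .minMaxFit(X[tr, glob, drop = FALSE])
      Xtr <- .minMaxApply(X[tr, glob, drop = FALSE], scl)
      Xte <- .minMaxApply(X[te, glob, drop = FALSE], scl)
      D2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), `+`) - 2 * tcrossprod(Xte, Xtr)
      D2[D2 < 0] <- 0
      pr <- .knnFromDist(D2, y[tr], k)
      wrong <- wrong + sum(pr$labels != y[te])
    }
    heldOut <- wrong / length(y)
  }

  r <- runOnce(X, y, foldSeed = seed)
  globalSel <- r$keep[r$sel$selected]
  provSel <- if (nrow(prov)) prov[globalSel, , drop = FALSE] else data.frame()
  new("SelectionResult",
      selected = as.integer(globalSel),
      lStar = as.integer(r$sel$lStar),
      errorCurve = r$sel$errorCurve,
      minError = r$sel$minError,
      chiOrder = as.integer(r$keep),
      ncaWeights = r$weights,
      provenance = provSel,
      scope = scope,
      heldOutError = heldOut,
      config = list(chiK = chiK, nBins = nBins, rangeLo = rangeLo,
                    rangeHi = rangeHi, folds = folds, k = k,
                    lambda = lambda, seed = as.integer(seed)))
}

#' Plot the prefix-size misclassification curve
#'
#' @param sr a [SelectionResult-class].
#' @param ... passed to [graphics::plot()].
#' @export
plotErrorCurve <- function(sr, ...) {
  stopifnot(is(sr, "SelectionResult"))
  l <- as.integer(names(sr@errorCurve))
  plot(l, sr@errorCurve, type = "l", xlab = "number of selected features",
       ylab = "CV misclassification rate", ...)
  points(sr@lStar, sr@minError, pch = 19, col = "red")
  abline(v = sr@lStar, lty = 3, col = "red")
  invisible(NULL)
}
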