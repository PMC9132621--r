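#' Shallow classifier specifications
#'
#' `classifierSpec()` builds a family + hyperparameter bundle;
#' `defaultClassifierSpec()` returns the reference defaults for each family:
#' kNN with k = 70, correlation distance and squared-inverse vote weights;
#' linear discriminant with gamma = 0 (no covariance regularization; a ridge
#' fallback engages only on singularity, with a warning); Gaussian
#' ("normal kernel") naive Bayes; Gaussian-kernel SVM with box constraint 3
#' and kernel scale 5.6; decision tree with deviance (cross-entropy) split
#' and at most 51 splits.
#'
#' @param family one of `"knn"`, `"ld"`, `"nb"`, `"svm"`, `"dt"`.
#' @param ... hyperparameter overrides (see Details per family).
#' @return a list with elements `family` and `params`.
#' @export
classifierSpec <- function(family = c("knn", "ld", "nb", "svm", "dt"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    knn = list(k = 70L, distance = "correlation", weight = "squared-inverse"),
    ld  = list(gamma = 0),
    nb  = list(varSmoothing = 1e-9),
    svm = list(boxConstraint = 3, kernelScale = 5.6),
    dt  = list(maxSplits = 51L, split = "deviance"))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown hyperparameters for ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  list(family = family, params = defaults)
}

#' @rdname classifierSpec
#' @export
defaultClassifierSpec <- function(family) classifierSpec(family)

# test x train distance matrix under the configured metric.
.classifierDist <- function(Xte, Xtr, distance) {
  switch(distance,
    euclidean = {
      D2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), `+`) -
        2 * tcrossprod(Xte, Xtr)
      sqrt(pmax(D2, 0))
    },
    correlation = {
      Cte <- Xte - rowMeans(Xte)
      Ctr <- Xtr - rowMeans(Xtr)
      nte <- sqrt(rowSums(Cte^2)); ntr <- sqrt(rowSums(Ctr^2))
      nte[nte == 0] <- Inf; ntr[ntr == 0] <- Inf
      1 - tcrossprod(Cte / nte, Ctr / ntr)
    },
    cosine = {
      nte <- sqrt(rowSums(Xte^2)); ntr <- sqrt(rowSums(Xtr^2))
      nte[nte == 0] <- Inf; ntr[ntr == 0] <- Inf
      1 - tcrossprod(Xte / nte, Xtr / ntr)
    },
    stop("unknown distance: ", distance, call. = FALSE))
}

.predictKnn <- function(params, Xtr, ytr, Xte) {
  k <- min(params$k, nrow(Xtr))
  D <- .classifierDist(Xte, Xtr, params$distance)
  lev <- levels(ytr)
  pos <- lev[2L]
  eps <- 1e-12
  labels <- character(nrow(Xte))
  scores <- numeric(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    o <- order(D[i, ])[seq_len(k)]
    wts <- switch(params$weight,
                  none = rep(1, k),
                  inverse = 1 / (D[i, o] + eps),
                  `squared-inverse` = 1 / (D[i, o]^2 + eps),
                  stop("unknown weight scheme: ", params$weight,
                       call. = FALSE))
    tot <- vapply(lev, function(cl) sum(wts[ytr[o] == cl]), 0)
    labels[i] <- lev[which.max(tot)]
    scores[i] <- tot[pos] / sum(tot)
  }
  list(labels = factor(labels, levels = lev), scores = scores)
}

# Pooled-covariance Gaussian linear discriminant; gamma in [0, 1] blends the
# pooled covariance toward a spherical target mean(diag(S)) * I. A ridge is
# added (with one warning) only if the blended covariance is still singular.
.predictLd <- function(params, Xtr, ytr, Xte) {
  lev <- levels(ytr)
  p <- ncol(Xtr)
  mus <- lapply(lev, function(cl) colMeans(Xtr[ytr == cl, , drop = FALSE]))
  nk <- as.numeric(table(ytr))
  Sw <- matrix(0, p, p)
  for (g in seq_along(lev)) {
    Xc <- sweep(Xtr[ytr == lev[g], , drop = FALSE], 2L, mus[[g]], "-")
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(Xtr) - length(lev))
  gamma <- params$gamma
  tr <- mean(diag(Sw))
  if (tr <= 0) tr <- 1
  S <- (1 - gamma) * Sw + gamma * tr * diag(p)
  ridge <- 1e-8 * tr
  Sinv <- NULL
  for (attempt in 1:12) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) { Sinv <- chol2inv(ch); break }
    if (attempt == 1L)
      warning("singular within-class covariance; adding ridge regularization",
              call. = FALSE)
    S <- S + ridge * diag(p)
    ridge <- ridge * 10
  }
  if (is.null(Sinv))
    stop("within-class covariance could not be regularized", call. = FALSE)
  priors <- nk / sum(nk)
  disc <- vapply(seq_along(lev), function(g) {
    a <- Sinv %*% mus[[g]]
    as.vector(Xte %*% a) - 0.5 * sum(mus[[g]] * a) + log(priors[g])
  }, numeric(nrow(Xte)))
  disc <- matrix(disc, nrow = nrow(Xte))
  post <- exp(disc - apply(disc, 1L, max))
  post <- post / rowSums(post)
  list(labels = factor(lev[max.col(disc, ties.method = "first")],
                       levels = lev),
       scores = post[, 2L])
}

# Gaussian naive Bayes with a variance-smoothing floor (a fraction of the
# largest overall feature variance is added to every class variance).
.predictNb <- function(params, Xtr, ytr, Xte) {
  lev <- levels(ytr)
  vs <- params$varSmoothing * max(apply(Xtr, 2L, var), .Machine$double.eps)
  logpost <- vapply(lev, function(cl) {
    Xc <- Xtr[ytr == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    v <- apply(Xc, 2L, var)
    v[!is.finite(v)] <- 0
    v <- v + vs + 1e-12
    ll <- -0.5 * colSums((t(Xte) - mu)^2 / v) - 0.5 * sum(log(2 * pi * v))
    ll + log(mean(ytr == cl))
  }, numeric(nrow(Xte)))
  logpost <- matrix(logpost, nrow = nrow(Xte))
  post <- exp(logpost - apply(logpost, 1L, max))
  post <- post / rowSums(post)
  list(labels = factor(lev[max.col(logpost, ties.method = "first")],
                       levels = lev),
       scores = post[, 2L])
}

.predictSvm <- function(params, Xtr, ytr, Xte) {
  lev <- levels(ytr)
  fit <- e1071::svm(Xtr, ytr, kernel = "radial",
                    cost = params$boxConstraint,
                    gamma = 1 / params$kernelScale^2,
                    scale = FALSE)
  pr <- predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 orients the decision value toward the first class in its header;
  # flip so larger = more likely the second factor level.
  hdr <- colnames(dv)[1L]
  sgn <- if (startsWith(hdr, paste0(lev[2L], "/"))) 1 else -1
  list(labels = factor(as.character(pr), levels = lev),
       scores = sgn * as.numeric(dv))
}

.predictDt <- function(params, Xtr, ytr, Xte) {
  lev <- levels(ytr)
  df <- data.frame(y = ytr, Xtr)
  colnames(df) <- c("y", paste0("f", seq_len(ncol(Xtr))))
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      parms = list(split = "information"),
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 4L,
                                                     minbucket = 2L))
  cp <- fit$cptable
  ok <- cp[cp[, "nsplit"] <= params$maxSplits, , drop = FALSE]
  if (nrow(ok) < nrow(cp))
    fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"] + 1e-12)
  nd <- data.frame(matrix(Xte, nrow = nrow(Xte)))
  colnames(nd) <- paste0("f", seq_len(ncol(Xte)))
  post <- predict(fit, nd, type = "prob")
  list(labels = factor(lev[max.col(post, ties.method = "first")],
                       levels = lev),
       scores = post[, lev[2L]])
}

#' Train a shallow classifier and predict a test set
#'
#' Deterministic fit given the spec and data. Scores are continuous
#' positive-class values usable for ROC: posterior probabilities (LD, NB,
#' DT), weighted vote shares (kNN) or decision values (SVM), oriented so
#' larger means the second factor level of `yTrain`.
#'
#' @param spec a [classifierSpec()].
#' @param XTrain,yTrain training matrix and binary labels (both classes must
#'   be present).
#' @param XTest test matrix.
#' @return list with `labels` (factor) and `scores` (numeric).
#' @export
trainPredict <- function(spec, XTrain, yTrain, XTest) {
  if (!is.matrix(XTrain)) XTrain <- as.matrix(XTrain)
  if (!is.matrix(XTest)) XTest <- as.matrix(XTest)
  yTrain <- as.factor(yTrain)
  if (nlevels(yTrain) != 2L || any(table(yTrain) < 1L) ||
      length(unique(as.character(yTrain))) < 2L)
    stop("training labels must contain both classes", call. = FALSE)
  fn <- switch(spec$family, knn = .predictKnn, ld = .predictLd,
               nb = .predictNb, svm = .predictSvm, dt = .predictDt,
               stop("unknown classifier family: ", spec$family,
                    call. = FALSE))
  fn(spec$params, XTrain, yTrain, XTest)
}

#' Stratified seeded cross-validation of a classifier
#'
#' Every observation is predicted exactly once by a model trained on the
#' other folds. Fold sizes differ by at most one; the assignment is fully
#' determined by `seed`. Fails loudly if a training fold would miss a class.
#'
#' @param spec a [classifierSpec()].
#' @param X numeric matrix (observations x features).
#' @param y binary labels.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(spec, X, y, folds = 10L, seed = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.factor(y)
  fold <- .stratifiedFolds(y, folds, seed)
  preds <- vector("list", max(fold))
  for (f in seq_len(max(fold))) {
    te <- which(fold == f)
    if (!length(te)) next
    tr <- which(fold != f)
    if (nlevels(droplevels(y[tr])) < 2L)
      stop("a training fold lost a class; use fewer folds", call. = FALSE)
    pr <- trainPredict(spec, X[tr, , drop = FALSE], y[tr],
                       X[te, , drop = FALSE])
    preds[[f]] <- data.frame(row = te, fold = f,
                             truth = as.character(y[te]),
                             predicted = as.character(pr$labels),
                             score = pr$scores)
  }
  pred <- do.call(rbind, preds)
  pred <- pred[order(pred$row), ]
  rownames(pred) <- NULL
  new("CVResult", family = spec$family, spec = spec$params,
      foldAssignments = fold, predictions = pred,
      pooledError = mean(pred$truth != pred$predicted))
}
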