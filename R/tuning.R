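# ---- search-space machinery --------------------------------------------
#
# A search space is a named list of dimensions:
#   list(type = "int", lo, hi)              integer range
#   list(type = "num", lo, hi, log = TRUE)  continuous, optionally log10
#   list(type = "cat", values = c(...))     categorical
# Each dimension is encoded into [0, 1] coordinates (one-hot for cat) for
# the Gaussian-process surrogate.

#' Default hyperparameter search spaces
#'
#' kNN: k in \[1, 100\] and the distance metric; SVM: log-scaled box
#' constraint in \[1e-2, 1e3\] and kernel scale in \[1e-2, 1e2\]; decision
#' tree: maximum splits in \[2, 200\]; linear discriminant: covariance
#' regularization gamma in \[0, 1\]; naive Bayes: log-scaled variance
#' smoothing in \[1e-12, 1e-1\].
#'
#' @param family classifier family.
#' @return a search-space list.
#' @export
defaultSearchSpace <- function(family) {
  switch(family,
    knn = list(k = list(type = "int", lo = 1, hi = 100),
               distance = list(type = "cat",
                               values = c("euclidean", "correlation",
                                          "cosine"))),
    svm = list(boxConstraint = list(type = "num", lo = 1e-2, hi = 1e3,
                                    log = TRUE),
               kernelScale = list(type = "num", lo = 1e-2, hi = 1e2,
                                  log = TRUE)),
    dt  = list(maxSplits = list(type = "int", lo = 2, hi = 200)),
    ld  = list(gamma = list(type = "num", lo = 0, hi = 1, log = FALSE)),
    nb  = list(varSmoothing = list(type = "num", lo = 1e-12, hi = 1e-1,
                                   log = TRUE)),
    stop("no default search space for family ", family, call. = FALSE))
}

.spaceDims <- function(space) {
  sum(vapply(space, function(d)
    if (d$type == "cat") length(d$values) else 1L, 1L))
}

# Cardinality of a fully discrete space; Inf if any continuous dimension.
.spaceCardinality <- function(space) {
  card <- 1
  for (d in space) {
    card <- card * switch(d$type,
      int = d$hi - d$lo + 1,
      cat = length(d$values),
      num = return(Inf))
  }
  card
}

.decodePoint <- function(space, u) {
  out <- list()
  i <- 0L
  for (nm in names(space)) {
    d <- space[[nm]]
    if (d$type == "cat") {
      k <- length(d$values)
      out[[nm]] <- d$values[which.max(u[i + seq_len(k)])]
      i <- i + k
    } else {
      i <- i + 1L
      x <- min(max(u[i], 0), 1)
      if (d$type == "int") {
        out[[nm]] <- as.integer(round(d$lo + x * (d$hi - d$lo)))
      } else if (isTRUE(d$log)) {
        out[[nm]] <- 10^(log10(d$lo) + x * (log10(d$hi) - log10(d$lo)))
      } else {
        out[[nm]] <- d$lo + x * (d$hi - d$lo)
      }
    }
  }
  out
}

.encodePoint <- function(space, params) {
  u <- numeric(0)
  for (nm in names(space)) {
    d <- space[[nm]]
    v <- params[[nm]]
    u <- c(u, switch(d$type,
      cat = as.numeric(d$values == v),
      int = if (d$hi > d$lo) (v - d$lo) / (d$hi - d$lo) else 0.5,
      num = if (isTRUE(d$log))
        (log10(v) - log10(d$lo)) / (log10(d$hi) - log10(d$lo))
      else (v - d$lo) / (d$hi - d$lo)))
  }
  pmin(pmax(u, 0), 1)
}

.enumerateSpace <- function(space) {
  grids <- lapply(space, function(d)
    switch(d$type, int = seq(d$lo, d$hi), cat = d$values,
           stop("cannot enumerate a continuous space", call. = FALSE)))
  g <- expand.grid(grids, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

.paramsKey <- function(params)
  paste(vapply(params, function(v)
    if (is.numeric(v)) format(v, digits = 12) else as.character(v), ""),
    collapse = "|")

# ---- Gaussian-process surrogate ----------------------------------------

.gpFit <- function(U, y, ell = 0.25) {
  sf2 <- max(var(y), 1e-10)
  D2 <- .pairwiseSqEuclidean(U)
  K <- sf2 * exp(-0.5 * D2 / ell^2) + diag(1e-6 * sf2 + 1e-12, nrow(U))
  mu <- mean(y)
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, y - mu, transpose = TRUE))
  list(U = U, ch = ch, alpha = alpha, mu = mu, sf2 = sf2, ell = ell)
}

.gpPredict <- function(fit, Unew) {
  D2 <- outer(rowSums(Unew^2), rowSums(fit$U^2), `+`) -
    2 * tcrossprod(Unew, fit$U)
  Ks <- fit$sf2 * exp(-0.5 * pmax(D2, 0) / fit$ell^2)
  mean <- fit$mu + as.vector(Ks %*% fit$alpha)
  v <- backsolve(fit$ch, t(Ks), transpose = TRUE)
  varp <- pmax(fit$sf2 - colSums(v^2), 1e-12)
  list(mean = mean, sd = sqrt(varp))
}

.expectedImprovement <- function(pred, fmin) {
  z <- (fmin - pred$mean) / pred$sd
  (fmin - pred$mean) * pnorm(z) + pred$sd * dnorm(z)
}

# ---- Bayesian optimization ---------------------------------------------

#' Bayesian hyperparameter tuning of a shallow classifier
#'
#' Sequential model-based optimization of the 10-fold cross-validated
#' misclassification rate: the family's default specification plus a seeded
#' Latin-hypercube design are evaluated first, then a Gaussian-process
#' surrogate with an expected-improvement acquisition proposes the remaining
#' evaluations up to `budget`. Fully discrete spaces whose cardinality fits
#' within the budget are enumerated exhaustively instead, and proposals
#' never repeat an evaluated configuration. One seeded fold partition is
#' used for all evaluations within a run, so traces are reproducible and
#' configurations are compared on identical folds.
#'
#' @param family classifier family (see [classifierSpec()]).
#' @param X numeric matrix (observations x features).
#' @param y binary labels.
#' @param budget total number of CV evaluations (default 100, >= 5).
#' @param seed seed controlling the design, proposals and fold partition.
#' @param folds CV folds per evaluation (default 10).
#' @param searchSpace optional space overriding [defaultSearchSpace()].
#' @return a [TuningTrace-class]; `tuningBest(trace)$spec` is the incumbent
#'   [classifierSpec()].
#' @export
bayesTune <- function(family, X, y, budget = 100L, seed = 1L, folds = 10L,
                      searchSpace = NULL) {
  budget <- .assertScalarCount(budget, "budget", lo = 5L)
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.factor(y)
  space <- if (is.null(searchSpace)) defaultSearchSpace(family) else searchSpace
  cvSeed <- seed + 104729L          # one partition per tuning run
  evalError <- function(params) {
    spec <- do.call(classifierSpec, c(list(family = family), params))
    suppressWarnings(
      crossValidate(spec, X, y, folds = folds, seed = cvSeed)@pooledError)
  }

  evaluated <- list()   # list of list(params, u, error)
  seen <- character(0)
  tryEval <- function(params) {
    key <- .paramsKey(params)
    if (key %in% seen) return(FALSE)
    err <- evalError(params)
    evaluated[[length(evaluated) + 1L]] <<-
      list(params = params, u = .encodePoint(space, params), error = err)
    seen <<- c(seen, key)
    TRUE
  }

  card <- .spaceCardinality(space)
  if (is.finite(card) && card <= budget) {
    for (params in .enumerateSpace(space)) tryEval(params)
  } else {
    # defaults first, so the incumbent can only match or beat them
    defParams <- classifierSpec(family)$params
    tryEval(defParams[names(space)])
    d <- .spaceDims(space)
    nInit <- min(budget - 1L, max(4L, 2L * d))
    initU <- .withSeed(seed, lhs::randomLHS(nInit, d))
    for (i in seq_len(nrow(initU))) tryEval(.decodePoint(space, initU[i, ]))
    it <- 0L
    while (length(evaluated) < budget && it < budget * 4L) {
      it <- it + 1L
      U <- do.call(rbind, lapply(evaluated, `[[`, "u"))
      errs <- vapply(evaluated, `[[`, 0, "error")
      fit <- .gpFit(U, errs)
      cand <- if (is.finite(card) && card <= 4096) {
        allPts <- .enumerateSpace(space)
        allPts <- allPts[!vapply(allPts, function(p)
          .paramsKey(p) %in% seen, TRUE)]
        if (!length(allPts)) break
        allPts
      } else {
        Uc <- .withSeed(seed + it, matrix(runif(512L * d), ncol = d))
        lapply(seq_len(nrow(Uc)), function(i) .decodePoint(space, Uc[i, ]))
      }
      Ucand <- do.call(rbind, lapply(cand, function(p) .encodePoint(space, p)))
      ei <- .expectedImprovement(.gpPredict(fit, Ucand), min(errs))
      ord <- order(-ei)
      placed <- FALSE
      for (j in ord[seq_len(min(16L, length(ord)))]) {
        if (tryEval(cand[[j]])) { placed <- TRUE; break }
      }
      if (!placed) {
        # fall back to a random unseen point
        for (r in seq_len(64L)) {
          pt <- .decodePoint(space,
                             .withSeed(seed + 7919L * it + r, runif(d)))
          if (tryEval(pt)) { placed <- TRUE; break }
        }
        if (!placed) break
      }
    }
  }

  errs <- vapply(evaluated, `[[`, 0, "error")
  iterDf <- do.call(rbind, lapply(evaluated, function(e)
    as.data.frame(e$params, stringsAsFactors = FALSE)))
  iterDf$error <- errs
  bi <- which.min(errs)
  best <- list(spec = do.call(classifierSpec,
                              c(list(family = family),
                                evaluated[[bi]]$params)),
               error = errs[bi])
  new("TuningTrace", family = family, iterations = iterDf, best = best,
      budget = budget, seed = as.integer(seed))
}
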