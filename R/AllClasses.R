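#' @title S4 containers for the pyramidal patch pipeline
#' @name pyratex-classes
#' @description
#' `ImagePyramid` holds the five average-pooled levels of a standardized
#' 256x256 image; `PatchSet` the 341 fixed-size 16x16 patches tiled from
#' those levels; `SelectionResult` the output of the two-stage chi-square +
#' iterative-NCA selector; `CVResult` one stratified cross-validation run of
#' a classifier; `TuningTrace` a Bayesian-optimization run; `EvalReport`
#' confusion-matrix metrics plus ROC/AUC.
NULL

#' @rdname pyratex-classes
#' @slot levels list of numeric matrices, finest (original) first.
#' @slot factors integer pooling block side per level.
#' @exportClass ImagePyramid
setClass("ImagePyramid",
         representation(levels = "list", factors = "integer"))

setValidity("ImagePyramid", function(object) {
  if (length(object@levels) != length(object@factors))
    return("levels and factors lengths differ")
  base <- nrow(object@levels[[1L]])
  for (i in seq_along(object@levels)) {
    m <- object@levels[[i]]
    if (!is.matrix(m) || !is.numeric(m)) return("levels must be numeric matrices")
    side <- base / object@factors[i]
    if (nrow(m) != side || ncol(m) != side)
      return(sprintf("level %d is %dx%d, expected side %g", i,
                     nrow(m), ncol(m), side))
  }
  TRUE
})

#' @rdname pyratex-classes
#' @slot patches numeric array `side x side x n`, level-then-row-major order.
#' @slot provenance data.frame with columns `patch`, `level` (0 = original),
#'   `row`, `col` (tile block coordinates within the level).
#' @slot patchSide integer tile side in pixels.
#' @exportClass PatchSet
setClass("PatchSet",
         representation(patches = "array", provenance = "data.frame",
                        patchSide = "integer"))

setValidity("PatchSet", function(object) {
  d <- dim(object@patches)
  if (length(d) != 3L) return("patches must be a 3-d array")
  if (d[1L] != object@patchSide || d[2L] != object@patchSide)
    return("patch array sides disagree with patchSide")
  if (d[3L] != nrow(object@provenance))
    return("provenance rows disagree with patch count")
  TRUE
})

#' @rdname pyratex-classes
#' @slot selected integer indices into the original feature space, ordered by
#'   descending NCA weight.
#' @slot lStar integer selected prefix length.
#' @slot errorCurve named numeric misclassification per candidate prefix size.
#' @slot minError numeric minimum of the curve.
#' @slot chiOrder integer chi-square ranking (top-k survivors, global indices).
#' @slot ncaWeights numeric NCA weight per survivor, same order as `chiOrder`.
#' @slot provenance data.frame describing selected features (may be empty).
#' @slot scope character, "whole" (selector fit once on all rows, as in the
#'   original procedure) or "fold" (refit inside each outer fold; leakage-free).
#' @slot heldOutError numeric; pooled outer-fold 1-NN error for scope "fold",
#'   `NA` otherwise.
#' @slot config list of selector settings and seeds.
#' @exportClass SelectionResult
setClass("SelectionResult",
         representation(selected = "integer", lStar = "integer",
                        errorCurve = "numeric", minError = "numeric",
                        chiOrder = "integer", ncaWeights = "numeric",
                        provenance = "data.frame", scope = "character",
                        heldOutError = "numeric", config = "list"))

setValidity("SelectionResult", function(object) {
  if (length(object@selected) != object@lStar)
    return("selected length differs from lStar")
  if (length(object@errorCurve) &&
      abs(object@minError - min(object@errorCurve)) > 1e-12)
    return("minError is not the minimum of errorCurve")
  TRUE
})

#' @rdname pyratex-classes
#' @slot family classifier family name.
#' @slot spec list of hyperparameters used.
#' @slot foldAssignments integer fold id per observation.
#' @slot predictions data.frame(row, fold, truth, predicted, score); `score`
#'   is the positive-class score used for ROC.
#' @slot pooledError numeric pooled misclassification rate.
#' @exportClass CVResult
setClass("CVResult",
         representation(family = "character", spec = "list",
                        foldAssignments = "integer",
                        predictions = "data.frame", pooledError = "numeric"))

setValidity("CVResult", function(object) {
  p <- object@predictions
  if (nrow(p) != length(object@foldAssignments))
    return("every observation must be predicted exactly once")
  err <- mean(as.character(p$truth) != as.character(p$predicted))
  if (abs(err - object@pooledError) > 1e-12)
    return("pooledError inconsistent with predictions")
  TRUE
})

#' @rdname pyratex-classes
#' @slot family classifier family tuned.
#' @slot iterations data.frame, one row per evaluated configuration, with the
#'   hyperparameters and the cross-validated `error`.
#' @slot best list(spec, error) incumbent.
#' @slot budget integer evaluation budget.
#' @slot seed integer seed the run was started from.
#' @exportClass TuningTrace
setClass("TuningTrace",
         representation(family = "character", iterations = "data.frame",
                        best = "list", budget = "integer", seed = "integer"))

setValidity("TuningTrace", function(object) {
  if (nrow(object@iterations) &&
      abs(object@best$error - min(object@iterations$error)) > 1e-12)
    return("best error is not the minimum over iterations")
  TRUE
})

#' @rdname pyratex-classes
#' @slot family label for the classifier evaluated.
#' @slot positiveClass level counted as positive.
#' @slot confusion list(tp, tn, fp, fn).
#' @slot metrics named numeric (percent): accuracy, precision, recall, f1 for
#'   the positive class.
#' @slot perClass matrix of precision/recall/f1 per class (percent).
#' @slot macro named numeric macro-averaged precision/recall/f1 (percent).
#' @slot foldAccuracy per-fold accuracy (proportion), possibly empty.
#' @slot roc data.frame(fpr, tpr).
#' @slot auc numeric area under the ROC curve.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(family = "character", positiveClass = "character",
                        confusion = "list", metrics = "numeric",
                        perClass = "matrix", macro = "numeric",
                        foldAccuracy = "numeric", roc = "data.frame",
                        auc = "numeric"))

setValidity("EvalReport", function(object) {
  cm <- object@confusion
  if (any(unlist(cm) < 0)) return("negative confusion counts")
  if (length(object@auc) && !is.na(object@auc) &&
      (object@auc < 0 || object@auc > 1))
    return("auc outside [0, 1]")
  TRUE
})

setMethod("show", "ImagePyramid", function(object) {
  cat("ImagePyramid with", length(object@levels), "levels; sides:",
      paste(vapply(object@levels, nrow, 1L), collapse = ", "), "\n")
})

setMethod("show", "PatchSet", function(object) {
  counts <- table(object@provenance$level)
  cat("PatchSet:", dim(object@patches)[3L], "patches of",
      object@patchSide, "x", object@patchSide, "\n  per level:",
      paste(sprintf("L%s=%d", names(counts), as.integer(counts)),
            collapse = ", "), "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@scope, " scope): ", object@lStar,
      " features selected, min CV misclassification ",
      signif(object@minError, 4), "\n", sep = "")
  if (!is.na(object@heldOutError))
    cat("  leakage-free held-out error:", signif(object@heldOutError, 4), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult [", object@family, "]: ",
      max(object@foldAssignments), "-fold, pooled error ",
      signif(object@pooledError, 4), "\n", sep = "")
})

setMethod("show", "TuningTrace", function(object) {
  cat("TuningTrace [", object@family, "]: ", nrow(object@iterations),
      " evaluations, best CV error ", signif(object@best$error, 4),
      "\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  m <- object@metrics
  cat("EvalReport [", object@family, "] positive = ", object@positiveClass,
      "\n", sep = "")
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%  AUC %.3f\n",
              m["accuracy"], m["precision"], m["recall"], m["f1"],
              object@auc))
})

#' Accessors for pipeline containers
#'
#' @param object an object of the matching pyratex class.
#' @return `pyramidLevels`: list of matrices; `patchArray`: the 16x16xN patch
#'   array; `patchProvenance`: data.frame of patch origins;
#'   `selectedFeatures`: integer indices; `errorCurve`: named numeric;
#'   `tuningBest`: list(spec, error); `reportMetrics`: named percent metrics.
#' @name accessors
NULL

#' @rdname accessors
#' @export
pyramidLevels <- function(object) object@levels

#' @rdname accessors
#' @export
patchArray <- function(object) object@patches

#' @rdname accessors
#' @export
patchProvenance <- function(object) object@provenance

#' @rdname accessors
#' @export
selectedFeatures <- function(object) object@selected

#' @rdname accessors
#' @export
errorCurve <- function(object) object@errorCurve

#' @rdname accessors
#' @export
tuningBest <- function(object) object@best

#' @rdname accessors
#' @export
reportMetrics <- function(object) object@metrics
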