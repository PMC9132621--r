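#' Pipeline commands
#'
#' Thin orchestration wrappers chaining the package's stages; each is also a
#' subcommand of the \command{pyratex} script installed under
#' \code{system.file("exec", package = "pyratex")}. All commands are
#' idempotent given fixed seeds and inputs.
#'
#' @name pipeline-commands
NULL

#' @describeIn pipeline-commands generate a synthetic dataset on disk
#'   (PNG images + `manifest.csv` + `config.json`).
#' @param outDir output directory.
#' @param nPerClass,side,separability,speckleLooks,seed see
#'   [generateSyntheticImages()].
#' @export
cmdSimulate <- function(outDir, nPerClass = 60L, side = 256L,
                        separability = 0.7, speckleLooks = 4, seed = 1L) {
  ds <- generateSyntheticImages(nPerClass, side, separability, speckleLooks,
                                seed, dir = outDir)
  message(sprintf("wrote %d images + manifest to %s",
                  length(ds$images), outDir))
  invisible(ds$manifest)
}

#' @describeIn pipeline-commands extract the per-image feature matrix from a
#'   manifest; aborts listing every unreadable image (no silent skips).
#' @param manifest path to a CSV with columns `path`, `label`, or the
#'   data.frame itself.
#' @param out output `.rds` path for the SummarizedExperiment; a JSON schema
#'   sidecar `<out>.json` records ids and column provenance summaries.
#' @export
cmdExtract <- function(manifest, out, side = 256L) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (!nrow(manifest)) stop("empty manifest", call. = FALSE)
  bad <- manifest$path[!file.exists(manifest$path)]
  if (length(bad))
    stop("unreadable images:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  se <- extractFeatures(manifest, side = side, verbose = TRUE)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  saveRDS(se, out)
  jsonlite::write_json(
    list(images = as.character(colData(se)$id),
         labels = as.character(colData(se)$label),
         nFeatures = nrow(se),
         families = as.list(table(rowData(se)$family))),
    paste0(out, ".json"), auto_unbox = TRUE)
  message(sprintf("extracted %d x %d feature matrix -> %s",
                  nrow(se), ncol(se), out))
  invisible(se)
}

#' @describeIn pipeline-commands run the two-stage selector; writes a JSON
#'   result and an error-curve plot next to it.
#' @param features path to the `.rds` written by [cmdExtract()] (or the
#'   SummarizedExperiment itself).
#' @param outPrefix path prefix for `<prefix>.json` / `<prefix>_curve.png`.
#' @param scope,chiK,rangeLo,rangeHi,folds see [cinca()].
#' @export
cmdSelect <- function(features, outPrefix, chiK = 1000L, rangeLo = 100L,
                      rangeHi = 1000L, folds = 10L, seed = 1L,
                      scope = "whole") {
  se <- if (is.character(features)) readRDS(features) else features
  sr <- cinca(se, chiK = chiK, rangeLo = rangeLo, rangeHi = rangeHi,
              folds = folds, seed = seed, scope = scope)
  message(sprintf("chi-square stage kept %d features; selected %d (min CV error %.4f)",
                  length(sr@chiOrder), sr@lStar, sr@minError))
  dir.create(dirname(outPrefix), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(selected = sr@selected, lStar = sr@lStar,
         errorCurve = as.list(sr@errorCurve), minError = sr@minError,
         scope = sr@scope, heldOutError = sr@heldOutError,
         config = sr@config),
    paste0(outPrefix, ".json"), auto_unbox = TRUE, digits = NA)
  grDevices::png(paste0(outPrefix, "_curve.png"), 700, 500)
  plotErrorCurve(sr, main = "prefix size vs CV misclassification")
  grDevices::dev.off()
  invisible(sr)
}

#' @describeIn pipeline-commands tune and evaluate the five classifier
#'   families on the selected features; writes a JSON report and ROC plots.
#' @param selection a [SelectionResult-class] or the JSON written by
#'   [cmdSelect()].
#' @param outDir report directory.
#' @param families classifier families to run.
#' @param budget Bayesian-optimization budget per family (default 20 for
#'   desk-scale runs; raise to 100 for the full schedule).
#' @export
cmdTrainEval <- function(features, selection, outDir, budget = 20L,
                         folds = 10L, seed = 1L,
                         families = c("knn", "ld", "nb", "svm", "dt")) {
  se <- if (is.character(features)) readRDS(features) else features
  sel <- if (is(selection, "SelectionResult")) selection@selected
         else as.integer(jsonlite::read_json(selection,
                                             simplifyVector = TRUE)$selected)
  X <- t(assay(se, "features"))[, sel, drop = FALSE]
  X <- .minMaxApply(X, .minMaxFit(X))
  y <- colData(se)$label
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  for (fam in families) {
    tt <- bayesTune(fam, X, y, budget = budget, seed = seed, folds = folds)
    cv <- suppressWarnings(
      crossValidate(tt@best$spec, X, y, folds = folds, seed = seed + 1L))
    rep <- evalReport(cv)
    reports[[fam]] <- rep
    grDevices::png(file.path(outDir, paste0("roc_", fam, ".png")), 600, 600)
    plotROC(rep)
    grDevices::dev.off()
    message(sprintf("%s: tuned CV accuracy %.2f%%, AUC %.3f",
                    fam, rep@metrics[["accuracy"]], rep@auc))
  }
  tab <- evalSummaryTable(reports)
  jsonlite::write_json(
    lapply(reports, function(r)
      list(metrics = as.list(r@metrics), confusion = r@confusion,
           auc = r@auc, positive = r@positiveClass)),
    file.path(outDir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  write.csv(tab, file.path(outDir, "evaluation.csv"), row.names = FALSE)
  invisible(reports)
}

#' @describeIn pipeline-commands simulate, extract, select and train-eval in
#'   one call under a single output directory.
#' @export
cmdRunAll <- function(outDir, nPerClass = 60L, separability = 0.7,
                      speckleLooks = 4, budget = 20L, folds = 10L,
                      seed = 1L) {
  cmdSimulate(file.path(outDir, "images"), nPerClass = nPerClass,
              separability = separability, speckleLooks = speckleLooks,
              seed = seed)
  se <- cmdExtract(file.path(outDir, "images", "manifest.csv"),
                   file.path(outDir, "features.rds"))
  sr <- cmdSelect(se, file.path(outDir, "selection"), folds = folds,
                  seed = seed)
  cmdTrainEval(se, sr, file.path(outDir, "reports"), budget = budget,
               folds = folds, seed = seed)
}
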