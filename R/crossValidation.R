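# class-stratified fold assignment, reproducible from the seed
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(as.character(labels))) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(sample(seq_len(k)), length(idx)))
    }
  })
  folds
}

#' Feasibility of a double nested stratified cross-validation
#'
#' A drug (or drug/cancer-type combination) supports the protocol only if
#' every inner validation split still contains both classes. Under
#' class-stratified splitting that holds iff, for each class, the smallest
#' outer training portion retains at least \code{innerFolds} members.
#'
#' @param labels two-class label factor.
#' @param outerFolds,innerFolds fold counts (defaults 5, 5).
#' @return logical(1).
#' @export
cvFeasible <- function(labels, outerFolds = 5, innerFolds = 5) {
  counts <- table(factor(as.character(labels),
                         levels = c("resistant", "sensitive")))
  if (any(counts < outerFolds)) return(FALSE)
  minTrain <- counts - ceiling(counts / outerFolds)
  all(minTrain >= innerFolds)
}

#' Repeated double nested stratified cross-validation
#'
#' Evaluates a predictor specification (see \code{\link{nbcPredictor}})
#' with the protocol: for each repeat, the samples are split into
#' \code{outerFolds} class-stratified folds; within each outer training
#' portion, an inner \code{innerFolds}-fold stratified cross-validation
#' selects the grid parameter (for the two-network classifier, the
#' correlation threshold) by mean balanced accuracy; the winner is refit on
#' the whole training portion and evaluated on the held-out outer fold.
#' Feature selection, network construction and all hyperparameter tuning
#' happen strictly inside the training portion -- test-fold samples never
#' reach any fit path. Fold metrics are averaged per repeat, then
#' summarized over repeats. All randomness derives from \code{(seed,
#' repeat, fold)}.
#'
#' @param expr expression matrix, genes x samples.
#' @param labels factor aligned to columns, levels resistant/sensitive.
#' @param predictor a predictor specification list.
#' @param outerFolds,innerFolds fold counts (defaults 5, 5).
#' @param nRepeats number of repeated partitionings (default 10; published
#'   protocols often use 100).
#' @param seed integer master seed.
#' @param computeAuc also compute a per-repeat ROC AUC from the
#'   predictor's decision scores pooled over outer folds (default
#'   \code{TRUE} when the predictor supplies \code{score}).
#' @return an \code{EvaluationReport}: list with \code{bac}, \code{bacSd},
#'   \code{mcc}, \code{mccSd}, \code{ambiguousRate}, \code{auc},
#'   \code{perRepeat} (data.frame), \code{bestParams} (tuning winners per
#'   repeat x fold), protocol counts and the seed.
#' @export
nestedCV <- function(expr, labels, predictor, outerFolds = 5,
                     innerFolds = 5, nRepeats = 10, seed = 1,
                     computeAuc = !is.null(predictor$score)) {
  labels <- factor(as.character(labels), levels = c("resistant", "sensitive"))
  stopifnot(is.matrix(expr), length(labels) == ncol(expr), !anyNA(labels))
  counts <- table(labels)
  if (any(counts < outerFolds))
    stop("infeasible: each class needs at least outerFolds = ", outerFolds,
         " samples (have ", paste(counts, collapse = "/"), ")")
  grid <- predictor$grid
  combos <- if (is.null(grid)) list(NULL)
            else apply(expand.grid(grid, KEEP.OUT.ATTRS = FALSE), 1L,
                       as.list)
  perRepeat <- vector("list", nRepeats)
  bestParams <- list()
  for (r in seq_len(nRepeats)) {
    folds <- stratifiedFolds(labels, outerFolds,
                             deriveSeed(seed, "outer", r))
    foldBac <- foldMcc <- foldAmb <- numeric(outerFolds)
    scores <- numeric(0); actual <- character(0)
    for (f in seq_len(outerFolds)) {
      trainIdx <- which(folds != f)
      testIdx <- which(folds == f)
      exprTr <- expr[, trainIdx, drop = FALSE]
      labTr <- labels[trainIdx]
      if (length(combos) > 1L) {
        if (!cvFeasible(labTr, outerFolds = innerFolds, innerFolds = 1L))
          stop("infeasible: an inner validation split would lack a class")
        inner <- stratifiedFolds(labTr, innerFolds,
                                 deriveSeed(seed, "inner", r, f))
        comboBac <- vapply(seq_along(combos), function(g) {
          bacs <- vapply(seq_len(innerFolds), function(fi) {
            ti <- inner != fi
            fit <- predictor$fit(exprTr[, ti, drop = FALSE], labTr[ti],
                                 combos[[g]],
                                 deriveSeed(seed, "fit", r, f, g, fi))
            pred <- predictor$predict(fit, exprTr[, !ti, drop = FALSE])
            balancedAccuracy(tabulateConfusion(labTr[!ti], pred))
          }, numeric(1))
          mean(bacs)
        }, numeric(1))
        best <- combos[[which.max(comboBac)]]  # first max = grid order
      } else {
        best <- combos[[1L]]
      }
      bestParams[[length(bestParams) + 1L]] <-
        c(list(repeatIdx = r, fold = f), best)
      fit <- predictor$fit(exprTr, labTr, best,
                           deriveSeed(seed, "outerfit", r, f))
      exprTe <- expr[, testIdx, drop = FALSE]
      pred <- predictor$predict(fit, exprTe)
      cm <- tabulateConfusion(labels[testIdx], pred)
      foldBac[f] <- balancedAccuracy(cm)
      foldMcc[f] <- suppressWarnings(mcc(cm))
      foldAmb[f] <- ambiguousRate(cm)
      if (computeAuc) {
        scores <- c(scores, predictor$score(fit, exprTe))
        actual <- c(actual, as.character(labels[testIdx]))
      }
    }
    perRepeat[[r]] <- data.frame(
      repeatIdx = r,
      bac = mean(foldBac),
      mcc = mean(foldMcc),
      ambiguousRate = mean(foldAmb),
      auc = if (computeAuc) rocAuc(scores, actual) else NA_real_
    )
  }
  perRepeat <- do.call(rbind, perRepeat)
  report <- list(
    predictor = predictor$name,
    bac = mean(perRepeat$bac),
    bacSd = sd(perRepeat$bac),
    mcc = mean(perRepeat$mcc),
    mccSd = sd(perRepeat$mcc),
    ambiguousRate = mean(perRepeat$ambiguousRate),
    auc = if (computeAuc) mean(perRepeat$auc) else NA_real_,
    perRepeat = perRepeat,
    bestParams = bestParams,
    outerFolds = outerFolds,
    innerFolds = innerFolds,
    nRepeats = nRepeats,
    seed = seed
  )
  class(report) <- "EvaluationReport"
  report
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: %s, %d x %d-fold nested CV, %d repeat(s), seed %d\n",
              x$predictor, x$outerFolds, x$innerFolds, x$nRepeats, x$seed))
  cat(sprintf("  BAC %.3f (SD %.3f)  MCC %.3f  ambiguous rate %.3f",
              x$bac, x$bacSd, x$mcc, x$ambiguousRate))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Fixed-parameter repeated stratified cross-validation
#'
#' Evaluates a predictor at fixed grid parameters (no inner tuning loop)
#' with repeated stratified k-fold cross-validation -- the protocol used to
#' profile accuracy across a correlation-threshold grid.
#'
#' @param expr,labels dataset as in \code{\link{nestedCV}}.
#' @param predictor a predictor specification list.
#' @param params named list of fixed parameter values passed to every fit.
#' @param folds fold count (default 5).
#' @param nRepeats repeated partitionings (default 10).
#' @param seed integer master seed.
#' @return list with \code{bac} (mean over repeats of fold-averaged
#'   balanced accuracy), \code{bacSd} and \code{perRepeat}.
#' @export
fixedParamCV <- function(expr, labels, predictor, params = NULL,
                         folds = 5, nRepeats = 10, seed = 1) {
  labels <- factor(as.character(labels), levels = c("resistant", "sensitive"))
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  repBac <- vapply(seq_len(nRepeats), function(r) {
    fid <- stratifiedFolds(labels, folds, deriveSeed(seed, "outer", r))
    bacs <- vapply(seq_len(folds), function(f) {
      tr <- fid != f
      fit <- predictor$fit(expr[, tr, drop = FALSE], labels[tr], params,
                           deriveSeed(seed, "fit", r, f))
      pred <- predictor$predict(fit, expr[, !tr, drop = FALSE])
      balancedAccuracy(tabulateConfusion(labels[!tr], pred))
    }, numeric(1))
    mean(bacs)
  }, numeric(1))
  list(bac = mean(repBac), bacSd = sd(repBac),
       perRepeat = data.frame(repeatIdx = seq_len(nRepeats), bac = repBac))
}

#' Per-group evaluation with a feasibility filter
#'
#' Runs \code{\link{nestedCV}} separately on each group of samples (e.g.
#' each cancer type for one drug). Groups for which the double nested
#' stratified protocol is infeasible -- some inner validation split would
#' contain no resistant or no sensitive cell line -- are reported as
#' \code{"insufficient"} instead of a report. Each group's result depends
#' only on its own samples.
#'
#' @param expr,labels dataset as in \code{\link{nestedCV}}.
#' @param grouping factor/character aligned to columns (e.g. cancer type).
#' @param predictor a predictor specification list.
#' @param outerFolds,innerFolds,nRepeats,seed protocol controls.
#' @return named list, one entry per group: an \code{EvaluationReport} or
#'   the string \code{"insufficient"}.
#' @export
stratifiedSubsetEval <- function(expr, labels, grouping, predictor,
                                 outerFolds = 5, innerFolds = 5,
                                 nRepeats = 10, seed = 1) {
  stopifnot(length(grouping) == ncol(expr))
  groups <- sort(unique(as.character(grouping)))
  out <- lapply(groups, function(g) {
    idx <- which(grouping == g)
    labG <- labels[idx]
    if (!cvFeasible(labG, outerFolds, innerFolds))
      return("insufficient")
    nestedCV(expr[, idx, drop = FALSE], labG, predictor,
             outerFolds = outerFolds, innerFolds = innerFolds,
             nRepeats = nRepeats, seed = deriveSeed(seed, "group", g))
  })
  names(out) <- groups
  out
}
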