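#' Pluggable predictor specifications for cross-validated evaluation
#'
#' \code{\link{nestedCV}} evaluates any predictor described by a list with:
#' \describe{
#'   \item{name}{character label.}
#'   \item{grid}{named list of tunable parameter values for the inner
#'     cross-validation loop, or \code{NULL} when nothing is tuned.}
#'   \item{fit}{\code{function(expr, labels, params, seed)} receiving the
#'     training expression matrix (genes x training samples only), the
#'     training labels, one grid combination and a derived seed; returns a
#'     fitted object.}
#'   \item{predict}{\code{function(fit, expr)} returning per-sample
#'     predictions in \{resistant, ambiguous, sensitive\}.}
#'   \item{score}{optional \code{function(fit, expr)} returning numeric
#'     decision values (larger = more sensitive) for ROC analysis.}
#' }
#'
#' \code{nbcPredictor} wraps the two-network classifier with its
#' correlation-threshold grid; \code{centroidPredictor} is a
#' mean-difference-only nearest-centroid baseline that ignores gene--gene
#' correlation, useful as a control for datasets whose signal lives in the
#' covariance structure.
#'
#' @param predictor \code{"ridge"} or \code{"svr"}.
#' @param nFeatures chi-square panel size m' (default 100).
#' @param tBins quantization terms for the chi-square score (default 10).
#' @param lambda ridge penalty (default 1e-3).
#' @param corrGrid correlation-threshold values tuned by the inner CV;
#'   default \code{seq(0.4, 0.94, by = 0.06)}.
#' @param svrGrid,svrFolds per-node SVR-RBF search grid and folds.
#' @param candidates optional gene list restricting feature selection.
#' @param featureMethod \code{"chi2"} (default) or \code{"random"} (null
#'   feature selection).
#' @return a predictor specification list (see Details).
#' @export
nbcPredictor <- function(predictor = c("ridge", "svr"), nFeatures = 100,
                         tBins = 10, lambda = 1e-3,
                         corrGrid = seq(0.4, 0.94, by = 0.06),
                         svrGrid = list(C = c(0.1, 1, 10),
                                        gamma = c(0.1, 1, 10),
                                        epsilon = 0.1),
                         svrFolds = 5, candidates = NULL,
                         featureMethod = c("chi2", "random")) {
  predictor <- match.arg(predictor)
  featureMethod <- match.arg(featureMethod)
  force(nFeatures); force(tBins); force(lambda); force(svrGrid)
  force(svrFolds); force(candidates)
  list(
    name = paste0("NBC(", predictor, ")"),
    grid = list(corrThreshold = corrGrid),
    fit = function(expr, labels, params, seed) {
      featureGenes <- if (featureMethod == "random")
        selectRandomGenes(expr, min(nFeatures, nrow(expr)), seed)$genes
      else NULL
      nbcTrain(expr, labels,
               corrThreshold = params$corrThreshold,
               predictor = predictor, nFeatures = nFeatures,
               tBins = tBins, lambda = lambda, svrGrid = svrGrid,
               svrFolds = svrFolds, candidates = candidates,
               featureGenes = featureGenes, seed = seed)
    },
    predict = function(fit, expr) as.character(classifyMatrix(fit, expr)$class),
    score = function(fit, expr) classifyMatrix(fit, expr)$score
  )
}

#' @rdname nbcPredictor
#' @export
centroidPredictor <- function(nFeatures = 100, tBins = 10) {
  force(nFeatures); force(tBins)
  list(
    name = "centroid",
    grid = NULL,
    fit = function(expr, labels, params, seed) {
      fs <- selectTopGenes(expr, labels, min(nFeatures, nrow(expr)),
                           t = tBins)
      sub <- expr[fs$genes, , drop = FALSE]
      list(genes = fs$genes,
           muS = rowMeans(sub[, labels == "sensitive", drop = FALSE]),
           muR = rowMeans(sub[, labels == "resistant", drop = FALSE]))
    },
    predict = function(fit, expr) {
      sub <- expr[fit$genes, , drop = FALSE]
      dS <- colSums((sub - fit$muS)^2)
      dR <- colSums((sub - fit$muR)^2)
      ifelse(dS < dR, "sensitive", "resistant")
    },
    score = function(fit, expr) {
      sub <- expr[fit$genes, , drop = FALSE]
      colSums((sub - fit$muR)^2) - colSums((sub - fit$muS)^2)
    }
  )
}
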