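#' CutoffPair: resistant and sensitive thresholds on the -log10 molar scale
#'
#' A pair of thresholds that partitions cell lines into resistant, ambiguous
#' and sensitive zones for one drug. Scores are \code{-log10} of the EC50 in
#' molar units, so an EC50 of 1 uM maps to 6. The resistant cutoff is always
#' less than or equal to the sensitive cutoff; scores strictly below the
#' resistant cutoff are resistant, strictly above the sensitive cutoff are
#' sensitive, everything in between (including exact ties) is ambiguous.
#'
#' @slot resistant numeric(1), resistant cutoff (-log10 molar).
#' @slot sensitive numeric(1), sensitive cutoff (-log10 molar).
#' @slot source character(1), \code{"clinical"} (anchored on a plasma Cmax)
#'   or \code{"statistical"} (anchored on the EC50 distribution).
#' @slot cmaxUM numeric, Cmax in uM for clinical pairs (length 0 otherwise).
#' @slot muUM,sigmaUM numeric, mean and SD of the EC50 values in uM for
#'   statistical pairs (length 0 otherwise).
#'
#' @seealso \code{\link{clinicalCutoffs}}, \code{\link{statisticalCutoffs}},
#'   \code{\link{assignLabels}}
#' @export
setClass("CutoffPair",
  representation(
    resistant = "numeric",
    sensitive = "numeric",
    source    = "character",
    cmaxUM    = "numeric",
    muUM      = "numeric",
    sigmaUM   = "numeric"
  )
)

setValidity("CutoffPair", function(object) {
  msg <- character()
  if (length(object@resistant) != 1L || length(object@sensitive) != 1L)
    msg <- c(msg, "resistant and sensitive must each have length 1")
  else if (object@resistant > object@sensitive + 1e-12)
    msg <- c(msg, "resistant cutoff must not exceed sensitive cutoff")
  if (!object@source %in% c("clinical", "statistical"))
    msg <- c(msg, "source must be 'clinical' or 'statistical'")
  if (length(msg)) msg else TRUE
})

#' ClassNetwork: a per-class gene correlation network with node predictors
#'
#' Undirected gene--gene graph for one response class. An edge joins two
#' genes when the absolute Pearson correlation of their expression vectors
#' across that class's training cell lines exceeds the correlation
#' threshold. After fitting, every node carries either a regression
#' predictor from its neighbours (degree >= 1) or a training-class mean
#' fallback (degree 0).
#'
#' @slot classLabel character(1), \code{"sensitive"} or \code{"resistant"}.
#' @slot genes character, ordered node set shared by both class networks.
#' @slot edges integer matrix with two columns, each row one undirected edge
#'   given as node indices with \code{edges[,1] < edges[,2]}.
#' @slot corrThreshold numeric(1) in (0, 1).
#' @slot predictors list, one entry per gene; \code{NULL} before fitting,
#'   otherwise a list describing the ridge coefficients or the SVR model
#'   together with the neighbour index set.
#' @slot fallbackMeans numeric, per-gene training-class mean expression.
#'
#' @seealso \code{\link{buildClassNetwork}}, \code{\link{fitRidgePredictors}},
#'   \code{\link{fitSvrPredictors}}
#' @export
setClass("ClassNetwork",
  representation(
    classLabel    = "character",
    genes         = "character",
    edges         = "matrix",
    corrThreshold = "numeric",
    predictors    = "list",
    fallbackMeans = "numeric"
  )
)

setValidity("ClassNetwork", function(object) {
  msg <- character()
  if (!object@classLabel %in% c("sensitive", "resistant"))
    msg <- c(msg, "classLabel must be 'sensitive' or 'resistant'")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique")
  e <- object@edges
  if (ncol(e) != 2L)
    msg <- c(msg, "edges must have two columns")
  else if (nrow(e)) {
    if (any(e[, 1L] >= e[, 2L]))
      msg <- c(msg, "edges must satisfy i < j (no self-loops, canonical order)")
    if (any(e < 1L) || any(e > length(object@genes)))
      msg <- c(msg, "edge indices out of range")
  }
  if (length(object@corrThreshold) != 1L ||
      object@corrThreshold <= 0 || object@corrThreshold >= 1)
    msg <- c(msg, "corrThreshold must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' NBCModel: the fitted two-network classifier
#'
#' The pair of class networks (sensitive, resistant) over one shared gene
#' panel, with the feature-selection record and the predictor kind. A test
#' expression vector is reconstructed through both networks; the class whose
#' reconstruction has the smaller mean squared error is predicted, with an
#' exact tie resolved to resistant.
#'
#' @slot sensitiveNet,resistantNet \code{ClassNetwork} objects sharing the
#'   same gene list and correlation threshold.
#' @slot featureGenes character, the selected gene panel (network node set).
#' @slot featureScores numeric, chi-square scores of the panel (may be empty
#'   for random selection).
#' @slot predictorKind character(1), \code{"ridge"} or \code{"svr"}.
#' @slot hyperparams list, \code{lambda} for ridge or the SVR search grid
#'   and per-node winners.
#'
#' @seealso \code{\link{nbcTrain}}, \code{\link{classifySample}}
#' @export
setClass("NBCModel",
  representation(
    sensitiveNet  = "ClassNetwork",
    resistantNet  = "ClassNetwork",
    featureGenes  = "character",
    featureScores = "numeric",
    predictorKind = "character",
    hyperparams   = "list"
  )
)

setValidity("NBCModel", function(object) {
  msg <- character()
  if (!identical(object@sensitiveNet@genes, object@resistantNet@genes))
    msg <- c(msg, "both class networks must share an identical gene list")
  if (!isTRUE(all.equal(object@sensitiveNet@corrThreshold,
                        object@resistantNet@corrThreshold)))
    msg <- c(msg, "both class networks must share the correlation threshold")
  if (!object@predictorKind %in% c("ridge", "svr"))
    msg <- c(msg, "predictorKind must be 'ridge' or 'svr'")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn CutoffPair-class resistant cutoff (-log10 molar).
#' @param object a \code{CutoffPair}.
#' @export
resistantCutoff <- function(object) object@resistant

#' @describeIn CutoffPair-class sensitive cutoff (-log10 molar).
#' @export
sensitiveCutoff <- function(object) object@sensitive

#' Genes of a network or model
#'
#' @param object a \code{ClassNetwork} or \code{NBCModel}.
#' @return character vector of gene symbols (node set / selected panel).
#' @export
networkGenes <- function(object) {
  if (is(object, "NBCModel")) return(object@featureGenes)
  object@genes
}

#' Edge list of a class network
#'
#' @param object a \code{ClassNetwork}.
#' @return a two-column character matrix of gene-symbol pairs, one row per
#'   undirected edge.
#' @export
networkEdges <- function(object) {
  stopifnot(is(object, "ClassNetwork"))
  e <- object@edges
  cbind(object@genes[e[, 1L]], object@genes[e[, 2L]])
}

#' Correlation threshold of a network or model
#'
#' @param object a \code{ClassNetwork} or \code{NBCModel}.
#' @export
corrThreshold <- function(object) {
  if (is(object, "NBCModel")) return(object@sensitiveNet@corrThreshold)
  object@corrThreshold
}

#' @describeIn NBCModel-class the predictor kind, \code{"ridge"} or
#'   \code{"svr"}.
#' @param object an \code{NBCModel}.
#' @export
predictorKind <- function(object) object@predictorKind

## ---- show methods ----

setMethod("show", "CutoffPair", function(object) {
  cat(sprintf("CutoffPair (%s): resistant %.3f / sensitive %.3f  [-log10 M]\n",
              object@source, object@resistant, object@sensitive))
  if (length(object@cmaxUM))
    cat(sprintf("  Cmax = %g uM\n", object@cmaxUM))
  if (length(object@muUM))
    cat(sprintf("  EC50 mean = %g uM, SD = %g uM\n",
                object@muUM, object@sigmaUM))
  invisible(NULL)
})

setMethod("show", "ClassNetwork", function(object) {
  fitted <- length(object@predictors) > 0L
  cat(sprintf(
    "ClassNetwork '%s': %d genes, %d edges (|r| > %.2f), predictors %s\n",
    object@classLabel, length(object@genes), nrow(object@edges),
    object@corrThreshold, if (fitted) "fitted" else "not fitted"))
  invisible(NULL)
})

setMethod("show", "NBCModel", function(object) {
  cat(sprintf("NBCModel (%s predictors), %d genes, corr threshold %.2f\n",
              object@predictorKind, length(object@featureGenes),
              corrThreshold(object)))
  cat(sprintf("  sensitive network: %d edges; resistant network: %d edges\n",
              nrow(object@sensitiveNet@edges),
              nrow(object@resistantNet@edges)))
  invisible(NULL)
})
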