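#' Build the correlation network for one response class
#'
#' Computes all pairwise Pearson correlations between gene expression
#' vectors across the class's cell lines and draws an undirected edge
#' between two genes when the absolute correlation strictly exceeds
#' \code{corrThreshold}. The correlation of a constant (zero-variance)
#' vector with anything is defined as 0, so constant genes are isolated
#' nodes. Predictors are not fitted here; see
#' \code{\link{fitRidgePredictors}} / \code{\link{fitSvrPredictors}}.
#'
#' @param classExpr expression submatrix for one class, genes x cell lines,
#'   with >= 3 cell lines.
#' @param corrThreshold threshold on \code{|r|}, strictly in (0, 1).
#' @param classLabel \code{"sensitive"} or \code{"resistant"}.
#' @return a \code{\linkS4class{ClassNetwork}} with edges but no fitted
#'   predictors.
#' @export
buildClassNetwork <- function(classExpr, corrThreshold,
                              classLabel = c("sensitive", "resistant")) {
  classLabel <- match.arg(classLabel)
  stopifnot(is.matrix(classExpr))
  if (ncol(classExpr) < 3L)
    stop("training error: need at least 3 cell lines in the ",
         classLabel, " class")
  if (corrThreshold <= 0 || corrThreshold >= 1)
    stop("corrThreshold must lie strictly in (0, 1)")
  genes <- rownames(classExpr)
  cm <- suppressWarnings(cor(t(classExpr)))
  cm[!is.finite(cm)] <- 0  # constant vectors: r defined as 0
  adj <- abs(cm) > corrThreshold
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  new("ClassNetwork", classLabel = classLabel, genes = genes,
      edges = edges, corrThreshold = corrThreshold,
      predictors = list(), fallbackMeans = rowMeans(classExpr))
}

# neighbor index sets per node from the canonical edge matrix
neighborSets <- function(network) {
  m <- length(network@genes)
  nb <- vector("list", m)
  e <- network@edges
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1L]; j <- e[r, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(x) if (is.null(x)) integer() else sort(x))
}

# Closed-form ridge with unpenalized intercept: center X and y, solve the
# penalized normal equations, recover the intercept from the means.
ridgeSolve <- function(X, y, lambda) {
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  ym <- mean(y)
  p <- ncol(X)
  beta <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, y - ym))
  list(coef = drop(beta), intercept = ym - sum(xm * beta))
}

#' Fit ridge predictors on every network node
#'
#' For each node with degree >= 1, fits a ridge regression (penalty
#' \code{lambda}, unpenalized intercept, no standardization) predicting the
#' node's expression from the expression of its network neighbours across
#' the class's training cell lines. Degree-0 nodes keep the training-class
#' mean as a constant fallback predictor.
#'
#' @param network a \code{\linkS4class{ClassNetwork}} built from
#'   \code{classExpr}.
#' @param classExpr the same class submatrix used to build the network.
#' @param lambda ridge penalty, > 0 (default 1e-3).
#' @return the network with fitted \code{predictors}.
#' @export
fitRidgePredictors <- function(network, classExpr, lambda = 1e-3) {
  stopifnot(is(network, "ClassNetwork"), is.matrix(classExpr),
            identical(rownames(classExpr), network@genes), lambda > 0)
  nb <- neighborSets(network)
  preds <- vector("list", length(network@genes))
  for (k in seq_along(preds)) {
    if (length(nb[[k]]) == 0L) {
      preds[[k]] <- list(kind = "fallback", neighbors = integer())
      next
    }
    X <- t(classExpr[nb[[k]], , drop = FALSE])
    fit <- ridgeSolve(X, classExpr[k, ], lambda)
    preds[[k]] <- list(kind = "ridge", neighbors = nb[[k]],
                       coef = fit$coef, intercept = fit$intercept)
  }
  network@predictors <- preds
  network
}

#' Fit SVR-RBF predictors on every network node
#'
#' For each node with degree >= 1, performs a grid search over
#' \code{(C, gamma, epsilon)} for an RBF-kernel support-vector regression
#' predicting the node from its neighbours. Each grid point is scored by
#' k-fold cross-validation mean squared error on the class's training cell
#' lines (one shared seeded fold split per call); the winner -- ties broken
#' by smallest \code{C}, then smallest \code{gamma} -- is refit on all
#' class samples. Degree-0 nodes keep the class-mean fallback. When the
#' class has fewer samples than \code{innerFolds} the fold count is
#' reduced with a warning.
#'
#' @param network a \code{\linkS4class{ClassNetwork}} built from
#'   \code{classExpr}.
#' @param classExpr the same class submatrix used to build the network.
#' @param grid list with numeric vectors \code{C}, \code{gamma},
#'   \code{epsilon}; defaults \code{C, gamma in \{0.1, 1, 10\}},
#'   \code{epsilon = 0.1}.
#' @param innerFolds folds for the per-node search (default 5).
#' @param seed integer seed controlling the shared fold split.
#' @return the network with fitted \code{predictors}; each SVR predictor
#'   records its winning hyperparameters.
#' @export
fitSvrPredictors <- function(network, classExpr,
                             grid = list(C = c(0.1, 1, 10),
                                         gamma = c(0.1, 1, 10),
                                         epsilon = 0.1),
                             innerFolds = 5, seed = 1) {
  stopifnot(is(network, "ClassNetwork"), is.matrix(classExpr),
            identical(rownames(classExpr), network@genes))
  n <- ncol(classExpr)
  if (innerFolds > n) {
    warning(sprintf("reducing per-node search folds from %d to %d (class size)",
                    innerFolds, n))
    innerFolds <- n
  }
  combos <- expand.grid(C = sort(grid$C), gamma = sort(grid$gamma),
                        epsilon = sort(grid$epsilon),
                        KEEP.OUT.ATTRS = FALSE)
  # order: smallest C first, then smallest gamma -- the tie-break order
  combos <- combos[order(combos$C, combos$gamma, combos$epsilon), ]
  folds <- withSeed(deriveSeed(seed, "svr-folds"),
                    sample(rep_len(seq_len(innerFolds), n)))
  nb <- neighborSets(network)
  preds <- vector("list", length(network@genes))
  for (k in seq_along(preds)) {
    if (length(nb[[k]]) == 0L) {
      preds[[k]] <- list(kind = "fallback", neighbors = integer())
      next
    }
    X <- t(classExpr[nb[[k]], , drop = FALSE])
    y <- classExpr[k, ]
    if (nrow(combos) == 1L) {
      best <- combos[1L, ]
    } else {
      cvErr <- vapply(seq_len(nrow(combos)), function(ci) {
        se <- 0
        for (f in seq_len(innerFolds)) {
          tr <- folds != f
          if (!any(tr) || all(tr)) next
          m <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                          type = "eps-regression", kernel = "radial",
                          cost = combos$C[ci], gamma = combos$gamma[ci],
                          epsilon = combos$epsilon[ci], scale = FALSE)
          pr <- predict(m, X[!tr, , drop = FALSE])
          se <- se + sum((pr - y[!tr])^2)
        }
        se / n
      }, numeric(1))
      best <- combos[which.min(cvErr), ]  # first minimum = smallest C, gamma
    }
    model <- e1071::svm(x = X, y = y, type = "eps-regression",
                        kernel = "radial", cost = best$C,
                        gamma = best$gamma, epsilon = best$epsilon,
                        scale = FALSE)
    preds[[k]] <- list(kind = "svr", neighbors = nb[[k]], model = model,
                       C = best$C, gamma = best$gamma,
                       epsilon = best$epsilon)
  }
  network@predictors <- preds
  network
}

#' Reconstruct an expression vector through a class network
#'
#' Applies each node's fitted predictor to the test sample's expression
#' restricted to that node's neighbours; degree-0 nodes return their
#' training-class mean. The output depends on entry \code{k} only through
#' the neighbour genes of node \code{k} (locality).
#'
#' @param network a fitted \code{\linkS4class{ClassNetwork}}.
#' @param x numeric vector aligned to \code{networkGenes(network)}.
#' @return numeric vector \code{y} of reconstructed expression levels.
#' @export
predictExpression <- function(network, x) {
  stopifnot(is(network, "ClassNetwork"))
  if (length(network@predictors) == 0L)
    stop("network has no fitted predictors")
  if (length(x) != length(network@genes))
    stop("contract error: x must have one entry per network gene")
  y <- numeric(length(x))
  for (k in seq_along(y)) {
    p <- network@predictors[[k]]
    y[k] <- switch(p$kind,
      fallback = network@fallbackMeans[k],
      ridge = p$intercept + sum(p$coef * x[p$neighbors]),
      svr = as.numeric(predict(p$model,
              matrix(x[p$neighbors], nrow = 1L))),
      stop("unknown predictor kind: ", p$kind))
  }
  y
}

#' Train an NBC model
#'
#' Convenience wrapper performing the full training pipeline on a labeled
#' two-class dataset: chi-square feature selection (unless a gene panel is
#' given), per-class network construction at one correlation threshold, and
#' per-node predictor fitting (ridge or SVR-RBF).
#'
#' @param expr expression matrix, genes x training cell lines.
#' @param labels factor aligned to columns with levels resistant/sensitive.
#' @param corrThreshold correlation threshold for both networks.
#' @param predictor \code{"ridge"} or \code{"svr"}.
#' @param nFeatures panel size m' for chi-square selection (default 100).
#' @param tBins quantization terms for the chi-square score (default 10).
#' @param lambda ridge penalty (default 1e-3).
#' @param svrGrid,svrFolds per-node SVR search grid and fold count (see
#'   \code{\link{fitSvrPredictors}}).
#' @param candidates optional gene list restricting feature selection.
#' @param featureGenes optional pre-selected panel (skips selection).
#' @param seed integer seed (SVR fold split).
#' @return an \code{\linkS4class{NBCModel}}.
#' @export
nbcTrain <- function(expr, labels, corrThreshold = 0.76,
                     predictor = c("ridge", "svr"),
                     nFeatures = 100, tBins = 10, lambda = 1e-3,
                     svrGrid = list(C = c(0.1, 1, 10),
                                    gamma = c(0.1, 1, 10), epsilon = 0.1),
                     svrFolds = 5, candidates = NULL,
                     featureGenes = NULL, seed = 1) {
  predictor <- match.arg(predictor)
  labels <- factor(as.character(labels), levels = c("resistant", "sensitive"))
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  if (anyNA(labels) || length(unique(labels)) < 2L)
    stop("training needs both resistant and sensitive samples")
  if (is.null(featureGenes)) {
    fs <- selectTopGenes(expr, labels, nFeatures, t = tBins,
                         candidates = candidates)
  } else {
    miss <- setdiff(featureGenes, rownames(expr))
    if (length(miss)) stop("featureGenes absent from matrix: ",
                           paste(head(miss, 3), collapse = ", "))
    fs <- list(genes = featureGenes, method = "fixed", scores = numeric())
  }
  sub <- expr[fs$genes, , drop = FALSE]
  fitNet <- function(classExpr, lab) {
    net <- buildClassNetwork(classExpr, corrThreshold, classLabel = lab)
    if (predictor == "ridge")
      fitRidgePredictors(net, classExpr, lambda)
    else
      fitSvrPredictors(net, classExpr, grid = svrGrid,
                       innerFolds = svrFolds,
                       seed = deriveSeed(seed, lab))
  }
  sNet <- fitNet(sub[, labels == "sensitive", drop = FALSE], "sensitive")
  rNet <- fitNet(sub[, labels == "resistant", drop = FALSE], "resistant")
  hyper <- if (predictor == "ridge") list(lambda = lambda)
           else list(grid = svrGrid, innerFolds = svrFolds)
  new("NBCModel", sensitiveNet = sNet, resistantNet = rNet,
      featureGenes = fs$genes, featureScores = fs$scores,
      predictorKind = predictor, hyperparams = hyper)
}

#' Classify one sample by the two-network MSE rule
#'
#' Reconstructs the sample's expression vector through both class networks
#' and predicts the class whose reconstruction has the smaller mean squared
#' error \eqn{\frac{1}{m'}\sum_k (x_k - y_k)^2}. An exact tie is resolved
#' to resistant (fixed, documented rule).
#'
#' @param model a fitted \code{\linkS4class{NBCModel}}.
#' @param x numeric vector aligned to \code{networkGenes(model)}.
#' @return list with \code{predictedClass}, \code{mseSensitive},
#'   \code{mseResistant}, \code{score} (\code{mseResistant -
#'   mseSensitive}; large positive favours sensitive) and
#'   \code{perGeneErrors} (matrix with columns \code{epsS}, \code{epsR}).
#' @export
classifySample <- function(model, x) {
  stopifnot(is(model, "NBCModel"))
  if (length(x) != length(model@featureGenes))
    stop("contract error: x must have one entry per model gene")
  ys <- predictExpression(model@sensitiveNet, x)
  yr <- predictExpression(model@resistantNet, x)
  epsS <- (x - ys)^2
  epsR <- (x - yr)^2
  mseS <- mean(epsS)
  mseR <- mean(epsR)
  list(
    predictedClass = if (mseS < mseR) "sensitive" else "resistant",
    mseSensitive = mseS,
    mseResistant = mseR,
    score = mseR - mseS,
    perGeneErrors = cbind(epsS = epsS, epsR = epsR)
  )
}

#' Classify a matrix of samples
#'
#' Applies \code{\link{classifySample}} to every column of an expression
#' matrix. Rows are matched to the model's gene panel by name.
#'
#' @param model a fitted \code{\linkS4class{NBCModel}}.
#' @param expr expression matrix, genes x samples, containing the model's
#'   genes.
#' @return data.frame with one row per sample: \code{class} (factor),
#'   \code{mseSensitive}, \code{mseResistant}, \code{score}.
#' @export
classifyMatrix <- function(model, expr) {
  stopifnot(is.matrix(expr))
  miss <- setdiff(model@featureGenes, rownames(expr))
  if (length(miss))
    stop("expression matrix lacks model gene(s): ",
         paste(head(miss, 3), collapse = ", "))
  sub <- expr[model@featureGenes, , drop = FALSE]
  res <- lapply(seq_len(ncol(sub)), function(j) classifySample(model, sub[, j]))
  data.frame(
    sample = colnames(sub),
    class = factor(vapply(res, `[[`, character(1), "predictedClass"),
                   levels = c("resistant", "sensitive")),
    mseSensitive = vapply(res, `[[`, numeric(1), "mseSensitive"),
    mseResistant = vapply(res, `[[`, numeric(1), "mseResistant"),
    score = vapply(res, `[[`, numeric(1), "score"),
    row.names = NULL
  )
}

#' Save / load a fitted NBC model
#'
#' Serializes the model (gene order, threshold, edge lists, predictor kind,
#' per-node coefficients or SVR models and hyperparameters, fallback means)
#' so a saved model classifies identically after reloading.
#'
#' @param model an \code{\linkS4class{NBCModel}}.
#' @param path file path.
#' @return \code{saveNBCModel} invisibly returns \code{path};
#'   \code{readNBCModel} returns the model.
#' @export
saveNBCModel <- function(model, path) {
  stopifnot(is(model, "NBCModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveNBCModel
#' @export
readNBCModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "NBCModel")) stop("file does not contain an NBCModel")
  validObject(model)
  model
}
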