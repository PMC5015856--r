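test_that("network edges follow |r| > threshold with constant vectors isolated", {
  classExpr <- rbind(g1 = c(1, 2, 3),
                     g2 = c(2, 4, 6),   # r = 1 with g1
                     g3 = c(5, 5, 5))   # constant: r defined as 0
  colnames(classExpr) <- paste0("c", 1:3)
  net <- buildClassNetwork(classExpr, 0.9, "sensitive")
  expect_equal(nrow(net@edges), 1)
  expect_identical(networkEdges(net), cbind("g1", "g2"))
  expect_error(buildClassNetwork(classExpr[, 1:2], 0.9), "at least 3")
  expect_error(buildClassNetwork(classExpr, 1.2), "strictly in")
})

test_that("edge sets equal a hand-coded all-pairs correlation scan", {
  for (seed in 1:5) {
    expr <- randomExpr(10, 8, seed = 100 + seed)
    for (th in c(0.3, 0.6)) {
      net <- buildClassNetwork(expr, th)
      got <- apply(net@edges, 1, paste, collapse = "-")
      want <- character()
      for (i in 1:9) for (j in (i + 1):10) {
        if (abs(pearsonByHand(expr[i, ], expr[j, ])) > th)
          want <- c(want, paste(i, j, sep = "-"))
      }
      expect_setequal(got, want)
    }
  }
})

test_that("raising the threshold never adds an edge", {
  expr <- randomExpr(12, 10, seed = 21)
  ths <- c(0.2, 0.4, 0.6, 0.8)
  edgeKeys <- lapply(ths, function(th)
    apply(buildClassNetwork(expr, th)@edges, 1, paste, collapse = "-"))
  for (k in 2:length(ths))
    expect_true(all(edgeKeys[[k]] %in% edgeKeys[[k - 1]]))
})

test_that("ridge predictors recover coefficients and obey the shrinkage limit", {
  set.seed(22)
  e1 <- rnorm(30)
  classExpr <- rbind(g1 = e1, g2 = 2 * e1)
  colnames(classExpr) <- paste0("c", 1:30)
  net <- buildClassNetwork(classExpr, 0.9)
  fitted <- fitRidgePredictors(net, classExpr, lambda = 1e-9)
  expect_equal(fitted@predictors[[2]]$coef, 2, tolerance = 1e-4,
               ignore_attr = TRUE)
  # independent oracle: augmented least squares on centered data
  expr <- randomExpr(6, 25, seed = 23)
  net2 <- fitRidgePredictors(buildClassNetwork(expr, 0.2), expr,
                             lambda = 0.5)
  for (k in 1:6) {
    p <- net2@predictors[[k]]
    if (p$kind != "ridge") next
    X <- t(expr[p$neighbors, , drop = FALSE])
    Xc <- scale(X, scale = FALSE)
    yc <- expr[k, ] - mean(expr[k, ])
    aug <- qr.solve(rbind(Xc, diag(sqrt(0.5), ncol(Xc))),
                    c(yc, rep(0, ncol(Xc))))
    expect_equal(unname(p$coef), unname(aug), tolerance = 1e-8)
  }
  # lambda -> infinity: coefficients vanish, prediction -> training mean
  heavy <- fitRidgePredictors(net, classExpr, lambda = 1e12)
  expect_equal(unname(heavy@predictors[[2]]$coef), 0, tolerance = 1e-6)
  expect_equal(predictExpression(heavy, c(10, 10))[2], mean(classExpr[2, ]),
               tolerance = 1e-6)
})

test_that("degree-0 nodes fall back to the class mean and reconstruction is local", {
  expr <- randomExpr(5, 20, seed = 24)
  expr["g05", ] <- rnorm(20, sd = 1e-8) + 100  # effectively uncorrelated
  net <- fitRidgePredictors(buildClassNetwork(expr, 0.999), expr)
  # threshold 0.999: everything isolated -> full fallback vector
  y <- predictExpression(net, rnorm(5))
  expect_equal(y, unname(rowMeans(expr)))
  # locality: output k depends only on neighbours of k
  net2 <- fitRidgePredictors(buildClassNetwork(expr[1:4, ], 0.2), expr[1:4, ])
  x <- rnorm(4)
  for (k in 1:4) {
    nbrs <- net2@predictors[[k]]$neighbors
    nonNbr <- setdiff(seq_len(4), c(k, nbrs))
    if (!length(nonNbr)) next
    x2 <- x
    x2[nonNbr[1]] <- x2[nonNbr[1]] + 5
    expect_equal(predictExpression(net2, x2)[k], predictExpression(net2, x)[k])
  }
  expect_error(predictExpression(net, rnorm(3)), "contract")
})

test_that("per-node SVR search is seeded, honours single-point grids, and beats ridge on a nonlinear node", {
  set.seed(25)
  e1 <- runif(60, -2, 2)
  e2 <- sin(2 * e1) + rnorm(60, sd = 0.05)
  classExpr <- rbind(g1 = e1, g2 = e2)
  colnames(classExpr) <- paste0("c", 1:60)
  net <- new("ClassNetwork", classLabel = "sensitive", genes = c("g1", "g2"),
             edges = matrix(c(1L, 2L), 1, 2), corrThreshold = 0.5,
             predictors = list(), fallbackMeans = rowMeans(classExpr))
  one <- fitSvrPredictors(net, classExpr,
                          grid = list(C = 1, gamma = 0.5, epsilon = 0.1),
                          seed = 3)
  expect_equal(one@predictors[[2]]$C, 1)
  expect_equal(one@predictors[[2]]$gamma, 0.5)
  a <- fitSvrPredictors(net, classExpr, seed = 9)
  b <- fitSvrPredictors(net, classExpr, seed = 9)
  expect_identical(
    a@predictors[[2]][c("C", "gamma", "epsilon")],
    b@predictors[[2]][c("C", "gamma", "epsilon")])
  # nonlinear relation: RBF regression reconstructs better than ridge
  svrFit <- a
  ridgeFit <- fitRidgePredictors(net, classExpr)
  mseOf <- function(fit) mean(vapply(seq_len(60), function(j)
    (predictExpression(fit, classExpr[, j])[2] - classExpr[2, j])^2,
    numeric(1)))
  expect_lt(mseOf(svrFit), mseOf(ridgeFit))
})

test_that("the MSE rule picks the smaller error and resolves ties to resistant", {
  model <- fallbackModel(meansS = c(0, 0), meansR = c(1, 1))
  resS <- classifySample(model, c(0.1, -0.1))
  expect_identical(resS$predictedClass, "sensitive")
  expect_lt(resS$mseSensitive, resS$mseResistant)
  # reported MSE is the mean of per-gene squared errors
  expect_equal(resS$mseSensitive, mean(resS$perGeneErrors[, "epsS"]),
               tolerance = 1e-9)
  # identical class networks -> exact tie -> resistant
  tie <- fallbackModel(meansS = c(0, 0), meansR = c(0, 0))
  expect_identical(classifySample(tie, c(2, 3))$predictedClass, "resistant")
})

test_that("swapping the training classes swaps every prediction", {
  ds <- smallDataset(seed = 26)  # 30 cell lines per class
  tr <- c(1:20, 31:50)
  te <- c(21:30, 51:60)
  swapped <- factor(ifelse(ds$labels == "sensitive", "resistant", "sensitive"),
                    levels = c("resistant", "sensitive"))
  mA <- nbcTrain(ds$expr[, tr], ds$labels[tr], corrThreshold = 0.7,
                 nFeatures = 10, seed = 4)
  mB <- nbcTrain(ds$expr[, tr], swapped[tr], corrThreshold = 0.7,
                 nFeatures = 10, seed = 4)
  pA <- classifyMatrix(mA, ds$expr[, te])
  pB <- classifyMatrix(mB, ds$expr[, te])
  noTie <- pA$score != 0
  expect_true(all(pA$class[noTie] != pB$class[noTie]))
})

test_that("held-out classification on correlation-structure data is near perfect", {
  ds <- generateDataset(syntheticSpec(seed = 42))
  tr <- c(1:70, 101:170)
  te <- setdiff(seq_len(200), tr)
  model <- nbcTrain(ds$expr[, tr], ds$labels[tr], corrThreshold = 0.76,
                    nFeatures = 30)
  cm <- netbc:::tabulateConfusion(ds$labels[te],
                                  classifyMatrix(model, ds$expr[, te])$class)
  expect_gt(balancedAccuracy(cm), 0.9)
})

test_that("a saved model classifies identically after reloading", {
  ds <- smallDataset(seed = 27)  # 30 cell lines per class
  tr <- c(1:25, 31:55)
  for (kind in c("ridge", "svr")) {
    model <- nbcTrain(ds$expr[, tr], ds$labels[tr], corrThreshold = 0.7,
                      predictor = kind, nFeatures = 8,
                      svrGrid = list(C = 1, gamma = 0.5, epsilon = 0.1),
                      seed = 5)
    path <- tempfile(fileext = ".rds")
    saveNBCModel(model, path)
    back <- readNBCModel(path)
    expect_identical(classifyMatrix(back, ds$expr),
                     classifyMatrix(model, ds$expr))
  }
})
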