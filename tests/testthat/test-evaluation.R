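# minimal hand-rolled predictor specs used to probe the CV machinery
constantPredictor <- function(class) {
  list(name = paste0("always-", class), grid = NULL,
       fit = function(expr, labels, params, seed) class,
       predict = function(fit, expr) rep(fit, ncol(expr)))
}

oraclePredictor <- function(truth) {
  list(name = "oracle", grid = NULL,
       fit = function(expr, labels, params, seed) NULL,
       predict = function(fit, expr) as.character(truth[colnames(expr)]))
}

test_that("a constant classifier scores BAC 0.5 and an oracle scores 1", {
  ds <- smallDataset(seed = 51, nPerClass = 20)
  rep1 <- nestedCV(ds$expr, ds$labels, constantPredictor("resistant"),
                   nRepeats = 2, seed = 3)
  expect_equal(rep1$bac, 0.5)
  expect_equal(rep1$ambiguousRate, 0)
  rep2 <- nestedCV(ds$expr, ds$labels, oraclePredictor(ds$labels),
                   nRepeats = 2, seed = 3)
  expect_equal(rep2$bac, 1)
  expect_equal(rep2$mcc, 1)
})

test_that("evaluation is bit-reproducible from the seed", {
  ds <- smallDataset(seed = 52, nPerClass = 15)
  pr <- nbcPredictor("ridge", nFeatures = 6, corrGrid = c(0.5, 0.7))
  a <- nestedCV(ds$expr, ds$labels, pr, nRepeats = 2, seed = 11)
  b <- nestedCV(ds$expr, ds$labels, pr, nRepeats = 2, seed = 11)
  expect_equal(a, b)
  c <- nestedCV(ds$expr, ds$labels, pr, nRepeats = 2, seed = 12)
  expect_false(identical(a$perRepeat, c$perRepeat))
})

test_that("no test-fold sample ever reaches a fit path", {
  ds <- smallDataset(seed = 53, nPerClass = 15)
  log <- new.env()
  log$pairs <- list()
  spy <- list(
    name = "spy", grid = list(knob = c(1, 2)),
    fit = function(expr, labels, params, seed) {
      list(ids = colnames(expr),
           maj = names(which.max(table(labels))))
    },
    predict = function(fit, expr) {
      log$pairs[[length(log$pairs) + 1L]] <-
        list(train = fit$ids, test = colnames(expr))
      rep(fit$maj, ncol(expr))
    })
  nestedCV(ds$expr, ds$labels, spy, nRepeats = 2, seed = 5)
  expect_gt(length(log$pairs), 0)
  for (p in log$pairs)
    expect_length(intersect(p$train, p$test), 0)
})

test_that("per-group evaluation filters infeasible groups and isolates the rest", {
  ds <- smallDataset(seed = 54, nPerClass = 20)
  n <- ncol(ds$expr)
  # group B holds resistant samples only -> the inner split must fail
  grouping <- rep("A", n)
  grouping[ds$labels == "resistant"][1:6] <- "B"
  pr <- constantPredictor("resistant")
  out <- stratifiedSubsetEval(ds$expr, ds$labels, grouping, pr,
                              nRepeats = 1, seed = 9)
  expect_identical(out$B, "insufficient")
  expect_s3_class(out$A, "EvaluationReport")
  # isolation: group A's report only depends on group A's samples
  idxA <- which(grouping == "A")
  alone <- nestedCV(ds$expr[, idxA], ds$labels[idxA], pr, nRepeats = 1,
                    seed = netbc:::deriveSeed(9, "group", "A"))
  expect_equal(out$A, alone)
})

test_that("feasibility requires every inner split to keep both classes", {
  lab <- function(r, s) factor(rep(c("resistant", "sensitive"), c(r, s)))
  expect_false(cvFeasible(lab(30, 0)))
  expect_false(cvFeasible(lab(30, 4)))    # fewer than outer folds
  expect_false(cvFeasible(lab(30, 6)))    # outer training keeps only 4-5
  expect_true(cvFeasible(lab(30, 7)))
  expect_true(cvFeasible(lab(30, 30)))
})

test_that("a repeat-averaged null dataset scores near chance", {
  ds <- smallDataset(seed = 55, nGenes = 15, nPerClass = 100, divergence = 1)
  permLabels <- netbc:::withSeed(13, sample(ds$labels))
  names(permLabels) <- names(ds$labels)
  pr <- nbcPredictor("ridge", nFeatures = 10, corrGrid = 0.7)
  rep0 <- nestedCV(ds$expr, permLabels, pr, nRepeats = 20, seed = 19,
                   computeAuc = FALSE)
  expect_gt(rep0$bac, 0.45)
  expect_lt(rep0$bac, 0.55)
})
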