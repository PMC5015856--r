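test_that("quantization splits the range into equal-width closed terms", {
  expect_identical(quantizeGene(c(0.1, 0.2, 0.9, 1.0), 2), c(1L, 1L, 2L, 2L))
  expect_identical(quantizeGene(rep(3.7, 5), 4), rep(1L, 5))
  # the maximum always lands in term t, never t + 1
  set.seed(12)
  for (t in c(2, 5, 10)) {
    v <- rnorm(30)
    q <- quantizeGene(v, t)
    expect_equal(q[which.max(v)], t)
    expect_true(all(q >= 1 & q <= t))
  }
})

test_that("chi-square score matches hand computation and detects independence", {
  lab <- c("resistant", "resistant", "sensitive", "sensitive")
  res <- chiSquareScore(c(0.1, 0.2, 0.9, 1.0), lab, t = 2)
  expect_equal(unname(res$observed), matrix(c(2, 0, 0, 2), 2, 2))
  expect_true(all(res$expected == 1))
  expect_equal(res$score, 4)
  # proportional counts across classes -> exact independence, score 0
  res0 <- chiSquareScore(c(1, 2, 1, 2), lab, t = 2)
  expect_equal(unname(res0$observed), matrix(1, 2, 2))
  expect_equal(res0$score, 0)
  expect_error(chiSquareScore(1:4, rep("resistant", 4)), "both classes")
})

test_that("chi-square score equals the brute-force double loop on random cases", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    t <- sample(2:5, 1)
    v <- rnorm(n)
    lab <- sample(c("resistant", "sensitive"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("resistant", "sensitive")
    expect_equal(chiSquareScore(v, lab, t)$score, chi2BruteForce(v, lab, t),
                 tolerance = 1e-9)
  }
})

test_that("chi-square score is invariant under sample permutation", {
  set.seed(14)
  v <- rnorm(12)
  lab <- rep(c("resistant", "sensitive"), 6)
  base <- chiSquareScore(v, lab, t = 4)$score
  for (i in 1:5) {
    p <- sample(12)
    expect_equal(chiSquareScore(v[p], lab[p], t = 4)$score, base,
                 tolerance = 1e-12)
  }
})

test_that("top-gene selection ranks by score with lexicographic tie-break", {
  lab <- c("resistant", "resistant", "sensitive", "sensitive")
  expr <- rbind(gC = c(0.1, 0.2, 0.9, 1.0),  # score 4
                gB = c(1, 2, 1, 2),          # score 0
                gA = c(0.1, 0.2, 0.9, 1.0))  # score 4, ties with gC
  colnames(expr) <- paste0("s", 1:4)
  fs <- selectTopGenes(expr, lab, 2, t = 2)
  expect_identical(fs$genes, c("gA", "gC"))
  expect_equal(unname(fs$scores), c(4, 4))
  # requesting more than available returns everything with a warning
  expect_warning(all3 <- selectTopGenes(expr, lab, 5, t = 2), "available")
  expect_equal(length(all3$genes), 3)
  # candidate restriction and the empty-intersection error
  fs2 <- selectTopGenes(expr, lab, 1, t = 2,
                        candidates = list(name = "listA",
                                          symbols = c("gB", "gZ")))
  expect_identical(fs2$genes, "gB")
  expect_error(selectTopGenes(expr, lab, 1, candidates = c("gX", "gY")),
               "selection error")
})

test_that("random gene selection is seeded and hits hypergeometric overlap", {
  expr <- randomExpr(1000, 4, seed = 15)
  a <- selectRandomGenes(expr, 100, seed = 77)
  b <- selectRandomGenes(expr, 100, seed = 77)
  expect_identical(a$genes, b$genes)
  expect_identical(sort(selectRandomGenes(expr, 1000, seed = 1)$genes),
                   sort(rownames(expr)))
  expect_error(selectRandomGenes(expr, 1001, seed = 1), "exceeds")
  # overlap of two independent draws of 100 from 1000: expect ~10 per pair
  overlaps <- vapply(1:100, function(i) {
    length(intersect(selectRandomGenes(expr, 100, seed = 2 * i)$genes,
                     selectRandomGenes(expr, 100, seed = 2 * i + 1)$genes))
  }, numeric(1))
  expect_gt(mean(overlaps), 7)
  expect_lt(mean(overlaps), 13)
})
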