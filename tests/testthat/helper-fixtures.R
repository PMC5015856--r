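# fixture builders shared across test files; everything is generated in
# code so the suite carries no data files

# small labeled two-class expression matrix with a correlation-structure
# signal, built from the package generator at reduced size
smallDataset <- function(seed = 1, nGenes = 20, nPerClass = 30, nBlocks = 4,
                         divergence = 1) {
  generateDataset(syntheticSpec(
    nGenes = nGenes, nPerClass = nPerClass, nBlocks = nBlocks,
    blockAssignmentDivergence = divergence, seed = seed))
}

writeExprFixture <- function(expr, dialect = "tsv") {
  path <- tempfile(fileext = paste0(".", dialect))
  writeExpressionMatrix(expr, path, dialect = dialect)
  path
}

randomExpr <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
         dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                         sprintf("s%02d", seq_len(nSamples))))
}

# independent Pearson correlation, written from the definition (the
# implementation under test goes through stats::cor)
pearsonByHand <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  den <- sqrt(sum(xm^2) * sum(ym^2))
  if (den == 0) return(0)
  sum(xm * ym) / den
}

# brute-force chi-square over quantized terms: independent double loop
# over the definition sum (A - E)^2 / E
chi2BruteForce <- function(values, labels, t) {
  terms <- {
    rng <- range(values)
    if (rng[1] == rng[2]) rep(1L, length(values))
    else pmin(floor((values - rng[1]) / (rng[2] - rng[1]) * t) + 1L, t)
  }
  classes <- c("resistant", "sensitive")
  n <- length(values)
  total <- 0
  for (j in seq_len(t)) {
    nj <- sum(terms == j)
    for (ci in 1:2) {
      A <- sum(terms == j & labels == classes[ci])
      E <- n * (nj / n) * (sum(labels == classes[ci]) / n)
      if (E > 0) total <- total + (A - E)^2 / E
    }
  }
  total
}

# degree-0-only network pair with distinct per-class means, for tests that
# need full manual control of per-gene errors
fallbackModel <- function(meansS, meansR, genes = paste0("g", seq_along(meansS))) {
  mkNet <- function(label, means) {
    new("ClassNetwork", classLabel = label, genes = genes,
        edges = matrix(integer(), 0, 2), corrThreshold = 0.5,
        predictors = replicate(length(genes),
          list(kind = "fallback", neighbors = integer()),
          simplify = FALSE),
        fallbackMeans = means)
  }
  new("NBCModel", sensitiveNet = mkNet("sensitive", meansS),
      resistantNet = mkNet("resistant", meansR),
      featureGenes = genes, featureScores = numeric(),
      predictorKind = "ridge", hyperparams = list(lambda = 1e-3))
}
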