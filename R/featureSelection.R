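#' Quantize an expression vector into equal-width terms
#'
#' Splits the observed range of a gene's expression values into \code{t}
#' equal-width intervals ("terms") and assigns each sample the index of the
#' interval containing its value. The last interval is closed so the
#' maximum maps to term \code{t}. A constant vector maps every sample to
#' term 1.
#'
#' @param values numeric expression vector.
#' @param t number of terms, >= 2.
#' @return integer vector of term indices in \code{[1, t]}.
#' @export
quantizeGene <- function(values, t) {
  stopifnot(is.numeric(values), t >= 2)
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(1L, length(values)))
  idx <- floor((values - rng[1L]) / (rng[2L] - rng[1L]) * t) + 1L
  idx[idx > t] <- as.integer(t)  # close the last interval
  as.integer(idx)
}

#' Chi-square class/term dependence score for one gene
#'
#' Quantizes the gene's expression into \code{t} terms, tabulates the
#' observed 2 x t class-by-term counts \eqn{A}, forms the expected counts
#' under independence \eqn{E_{c,j} = n P_{class}(c) P_{term}(j)}, and
#' returns \eqn{\chi^2 = \sum_{j}\sum_{c} (A_{c,j}-E_{c,j})^2 / E_{c,j}}.
#' Cells with \eqn{E = 0} (empty terms) force \eqn{A = 0} too and
#' contribute 0. The higher the score, the more the quantized expression
#' level depends on the class.
#'
#' @param values numeric expression vector.
#' @param labels factor/character vector with exactly the two classes
#'   \code{resistant} and \code{sensitive}, aligned to \code{values}.
#' @param t number of quantization terms (default 10).
#' @return list with \code{observed} (2 x t matrix, rows resistant,
#'   sensitive), \code{expected}, \code{t} and \code{score}.
#' @examples
#' chiSquareScore(c(0.1, 0.2, 0.9, 1.0),
#'                c("resistant", "resistant", "sensitive", "sensitive"),
#'                t = 2)$score  # 4
#' @export
chiSquareScore <- function(values, labels, t = 10) {
  labels <- as.character(labels)
  classes <- c("resistant", "sensitive")
  if (!all(labels %in% classes))
    stop("labels must be 'resistant' or 'sensitive'")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to score class/term dependence")
  stopifnot(length(values) == length(labels))
  n <- length(values)
  terms <- quantizeGene(values, t)
  A <- matrix(0, 2L, t, dimnames = list(classes, NULL))
  for (c_i in 1:2) {
    tab <- tabulate(terms[labels == classes[c_i]], nbins = t)
    A[c_i, ] <- tab
  }
  pTerm <- colSums(A) / n
  pClass <- rowSums(A) / n
  E <- n * outer(pClass, pTerm)
  contrib <- (A - E)^2 / E
  contrib[E == 0] <- 0
  list(observed = A, expected = E, t = t, score = sum(contrib))
}

#' Select the top genes by chi-square score
#'
#' Scores every candidate gene with \code{\link{chiSquareScore}} on the
#' training samples and returns the \code{mPrime} highest-scoring genes.
#' Ties are broken lexicographically by gene symbol for reproducibility.
#' Candidates can be restricted to a supplied gene list (e.g. pro- or
#' anti-apoptotic genes); scoring and ranking are unchanged, only the
#' candidate pool shrinks.
#'
#' @param expr expression matrix, genes x samples (training samples only --
#'   feature selection must never see test samples).
#' @param labels two-class factor aligned to the columns.
#' @param mPrime number of genes to select.
#' @param t quantization terms (default 10).
#' @param candidates optional gene list (as from \code{\link{readGeneList}})
#'   or character vector restricting the candidate pool.
#' @return list with \code{genes} (ordered selected symbols),
#'   \code{method}, and \code{scores} (named chi-square scores of the
#'   selection).
#' @export
selectTopGenes <- function(expr, labels, mPrime, t = 10, candidates = NULL) {
  stopifnot(is.matrix(expr), mPrime >= 1)
  pool <- rownames(expr)
  method <- "chi2"
  if (!is.null(candidates)) {
    syms <- if (is.list(candidates)) candidates$symbols else candidates
    method <- if (is.list(candidates) && !is.null(candidates$name))
      candidates$name else "gene_list"
    pool <- intersect(pool, syms)
    if (!length(pool))
      stop("selection error: no candidate gene present in the expression matrix")
  }
  scores <- vapply(pool, function(g)
    chiSquareScore(expr[g, ], labels, t)$score, numeric(1))
  ord <- order(-scores, pool)
  if (mPrime >= length(pool)) {
    if (mPrime > length(pool))
      warning(sprintf("only %d candidate gene(s) available; returning all",
                      length(pool)))
    mPrime <- length(pool)
  }
  sel <- ord[seq_len(mPrime)]
  list(genes = pool[sel], method = method, scores = scores[sel])
}

#' Select a random gene panel (null baseline)
#'
#' Uniform sample of \code{mPrime} genes without replacement, reproducible
#' from the seed. Serves as the null hypothesis against informed feature
#' selection.
#'
#' @param expr expression matrix, genes x samples.
#' @param mPrime number of genes, <= number of rows.
#' @param seed integer seed.
#' @return list with \code{genes}, \code{method = "random"}, and empty
#'   \code{scores}.
#' @export
selectRandomGenes <- function(expr, mPrime, seed) {
  stopifnot(is.matrix(expr))
  if (mPrime > nrow(expr))
    stop("mPrime exceeds the number of genes")
  genes <- withSeed(seed, sample(rownames(expr), mPrime))
  list(genes = genes, method = "random", scores = numeric())
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never perturbs user randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic sub-seed derivation: one top-level seed fans out into
# distinct streams per (purpose, index) so module draws never collide.
deriveSeed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    pv <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
          else as.double(p)
    h <- (h * 1103515245 + pv * 12345 + 1) %% 2147483647
  }
  as.integer(h)
}
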