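#' Specification for the synthetic two-class expression generator
#'
#' Describes a dataset with the structure the two-network classifier
#' assumes: genes fall into correlated blocks driven by shared latent
#' factors, and the two response classes differ in which genes share a
#' block -- not in any per-gene mean or variance. Expression for gene
#' \eqn{g} in block \eqn{b} is
#' \deqn{x_g = \sqrt{\rho}\, f_b + \mathrm{noiseSd} \cdot \varepsilon}
#' with standard normal factor and noise, so with the default
#' \code{noiseSd = sqrt(1 - withinBlockCorr)} every gene has zero mean and
#' unit variance in both classes and the within-block correlation equals
#' \code{withinBlockCorr}. A fraction \code{blockAssignmentDivergence} of
#' genes is moved to a different block in the resistant class; at 0 the two
#' classes are exchangeable, at 1 every gene changes block membership.
#'
#' EC50 values are drawn on the \code{-log10} molar score scale from class
#' centers placed symmetrically around the midpoint of the supplied cutoff
#' pair, \code{ec50Separation} apart, with SD \code{ec50Sd}; mapping back
#' through \code{10^(6 - score)} gives concentrations in uM whose labeling
#' under the cutoffs yields all three zones.
#'
#' @param nGenes number of genes (default 60).
#' @param nPerClass cell lines per class (default 100).
#' @param nBlocks number of correlated blocks (default 6).
#' @param withinBlockCorr target within-block Pearson correlation in
#'   (0, 1), default 0.9.
#' @param blockAssignmentDivergence fraction of genes whose block differs
#'   between classes, in [0, 1], default 1.
#' @param noiseSd residual SD; default \code{sqrt(1 - withinBlockCorr)}.
#' @param ec50Separation gap between class EC50 centers in -log10 units
#'   (default 2).
#' @param ec50Sd SD of the score draw (default 0.5).
#' @param seed integer seed; all generator randomness derives from it.
#' @return validated spec list of class \code{syntheticSpec}.
#' @export
syntheticSpec <- function(nGenes = 60, nPerClass = 100, nBlocks = 6,
                          withinBlockCorr = 0.9,
                          blockAssignmentDivergence = 1,
                          noiseSd = sqrt(1 - withinBlockCorr),
                          ec50Separation = 2, ec50Sd = 0.5, seed = 1) {
  if (nBlocks < 1 || nGenes < nBlocks)
    stop("spec error: need nGenes >= nBlocks >= 1")
  if (withinBlockCorr <= 0 || withinBlockCorr >= 1)
    stop("spec error: withinBlockCorr must lie strictly in (0, 1)")
  spec <- list(nGenes = nGenes, nPerClass = nPerClass, nBlocks = nBlocks,
               withinBlockCorr = withinBlockCorr,
               blockAssignmentDivergence = blockAssignmentDivergence,
               noiseSd = noiseSd, ec50Separation = ec50Separation,
               ec50Sd = ec50Sd, seed = seed)
  if (blockAssignmentDivergence < 0 || blockAssignmentDivergence > 1)
    stop("spec error: blockAssignmentDivergence must lie in [0, 1]")
  if (noiseSd < 0 || ec50Sd <= 0 || ec50Separation < 0)
    stop("spec error: noiseSd >= 0, ec50Sd > 0, ec50Separation >= 0 required")
  structure(spec, class = "syntheticSpec")
}

#' Generate a synthetic two-class drug-response dataset
#'
#' Draws expression and EC50 data according to a \code{\link{syntheticSpec}}:
#' the classes share per-gene means and variances and differ only in their
#' gene--gene correlation structure (unless the divergence is 0, in which
#' case they are exchangeable). Fully reproducible from the spec's seed.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param cutoffs a \code{\linkS4class{CutoffPair}} the EC50 draw is
#'   centered on; default \code{clinicalCutoffs(1, clampFloor = NULL)}.
#' @param drug drug name written into the response table.
#' @return list with \code{expr} (genes x 2*nPerClass matrix),
#'   \code{response} (cell_line/drug/ec50_um data.frame), \code{labels}
#'   (true class factor aligned to columns), \code{blocks} (per-class
#'   block assignment vectors), \code{cutoffs} and \code{spec}.
#' @export
generateDataset <- function(spec, cutoffs = clinicalCutoffs(1, clampFloor = NULL),
                            drug = "synthetic-drug") {
  stopifnot(inherits(spec, "syntheticSpec"), is(cutoffs, "CutoffPair"))
  nG <- spec$nGenes; nC <- spec$nPerClass; nB <- spec$nBlocks
  genes <- sprintf("g%03d", seq_len(nG))
  cells <- sprintf("CL%04d", seq_len(2L * nC))
  labels <- factor(rep(c("sensitive", "resistant"), each = nC),
                   levels = c("resistant", "sensitive"))
  # Sensitive blocks are contiguous runs; divergent genes are re-assigned in
  # the resistant class by a cyclic interleave, which scatters each
  # sensitive block across all resistant blocks (new co-membership), rather
  # than a label shift (which would only rename blocks).
  blocksS <- sort(rep_len(seq_len(nB), nG))
  cyclic <- rep_len(seq_len(nB), nG)
  nDiv <- round(spec$blockAssignmentDivergence * nG)
  divGenes <- withSeed(deriveSeed(spec$seed, "divergence"),
                       sample(seq_len(nG), nDiv))
  blocksR <- blocksS
  if (nB > 1L && nDiv > 0L)
    blocksR[divGenes] <- cyclic[divGenes]
  loading <- sqrt(spec$withinBlockCorr)
  drawClass <- function(blocks, streamName) {
    withSeed(deriveSeed(spec$seed, streamName), {
      f <- matrix(rnorm(nB * nC), nB, nC)
      eps <- matrix(rnorm(nG * nC), nG, nC)
      loading * f[blocks, , drop = FALSE] + spec$noiseSd * eps
    })
  }
  expr <- cbind(drawClass(blocksS, "expr-sensitive"),
                drawClass(blocksR, "expr-resistant"))
  dimnames(expr) <- list(genes, cells)
  mid <- (resistantCutoff(cutoffs) + sensitiveCutoff(cutoffs)) / 2
  centers <- ifelse(labels == "sensitive",
                    mid + spec$ec50Separation / 2,
                    mid - spec$ec50Separation / 2)
  score <- withSeed(deriveSeed(spec$seed, "ec50"),
                    rnorm(length(centers), mean = centers, sd = spec$ec50Sd))
  response <- data.frame(cell_line = cells, drug = drug,
                         ec50_um = 10^(6 - score),
                         stringsAsFactors = FALSE)
  list(expr = expr, response = response,
       labels = setNames(labels, cells),
       blocks = list(sensitive = blocksS, resistant = blocksR),
       cutoffs = cutoffs, spec = spec)
}

#' Mean within-block absolute correlation (generator self-check)
#'
#' Average absolute pairwise Pearson correlation over gene pairs sharing a
#' block; used to verify the generator realizes its target within-block
#' correlation. Returns \code{NA} when every block is a singleton (no
#' within-block pair exists).
#'
#' @param exprClass expression submatrix for one class, genes x samples.
#' @param blocks integer block assignment aligned to rows.
#' @return mean within-block |r|, or \code{NA_real_}.
#' @export
empiricalBlockCorrelation <- function(exprClass, blocks) {
  stopifnot(is.matrix(exprClass), length(blocks) == nrow(exprClass))
  vals <- numeric(0)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    if (length(idx) < 2L) next
    cm <- cor(t(exprClass[idx, , drop = FALSE]))
    vals <- c(vals, abs(cm[upper.tri(cm)]))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
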