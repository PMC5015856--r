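#' Per-gene prediction success rate
#'
#' Quantifies each panel gene's contribution to correct classification.
#' For a test sample with true class resistant, gene \eqn{g} contributes
#' when its resistant-network reconstruction error is strictly smaller
#' than its sensitive-network error (\eqn{\epsilon_r < \epsilon_s}), and
#' symmetrically for sensitive samples. The prediction success rate of
#' \eqn{g} is the fraction of test samples for which it contributes. Genes
#' with high rates consistently side with the true class in the MSE vote
#' and are candidates for follow-up investigation.
#'
#' @param model a fitted \code{\linkS4class{NBCModel}}.
#' @param expr expression matrix, genes x test samples, containing the
#'   model's gene panel.
#' @param labels true classes of the test samples (resistant/sensitive),
#'   aligned to columns.
#' @return data.frame with one row per panel gene: \code{gene},
#'   \code{successRate} in [0, 1], \code{nTestSamples}; sorted by
#'   decreasing rate, ties in gene order.
#' @export
predictionSuccessRate <- function(model, expr, labels) {
  stopifnot(is(model, "NBCModel"), is.matrix(expr),
            length(labels) == ncol(expr), ncol(expr) >= 1L)
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("resistant", "sensitive")))
  genes <- model@featureGenes
  sub <- expr[genes, , drop = FALSE]
  contrib <- integer(length(genes))
  for (j in seq_len(ncol(sub))) {
    res <- classifySample(model, sub[, j])
    eps <- res$perGeneErrors
    ok <- if (labels[j] == "resistant") eps[, "epsR"] < eps[, "epsS"]
          else eps[, "epsS"] < eps[, "epsR"]
    contrib <- contrib + as.integer(ok)
  }
  out <- data.frame(gene = genes,
                    successRate = contrib / ncol(sub),
                    nTestSamples = ncol(sub),
                    row.names = NULL)
  out[order(-out$successRate, seq_len(nrow(out))), , drop = FALSE]
}
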