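#' Clinically anchored resistant/sensitive cutoffs
#'
#' Converts a drug's average maximal plasma concentration (Cmax, uM) into a
#' pair of thresholds on the -log10 molar scale:
#' \deqn{resistant = -log10(Cmax \cdot 1.5 \cdot 10^{-6}), \quad
#'       sensitive = -log10(Cmax / 1.5 \cdot 10^{-6})}
#' (the \code{+6} term in the uM form is the uM-to-molar conversion). The
#' two values always differ by \code{2*log10(1.5) ~ 0.352}. A cell line
#' whose -log10 molar EC50 falls below the resistant cutoff needs more than
#' 1.5x the clinical exposure for a half-maximal effect; above the
#' sensitive cutoff it responds below 1/1.5x that exposure.
#'
#' With \code{clampFloor} set (default 5, i.e. -log10 of a 10 uM maximal
#' screened dose) each cutoff is raised to at least the floor, which is how
#' published tables handle drugs whose Cmax-derived cutoff would fall below
#' the assay's tested concentration range.
#'
#' @param cmaxUM Cmax in uM, strictly positive.
#' @param clampFloor minimum cutoff value (-log10 molar) or \code{NULL} to
#'   disable clamping. Default 5.
#' @return a \code{\linkS4class{CutoffPair}}.
#' @examples
#' clinicalCutoffs(1.0, clampFloor = NULL)  # 5.824 / 6.176
#' @export
clinicalCutoffs <- function(cmaxUM, clampFloor = 5) {
  if (!is.numeric(cmaxUM) || length(cmaxUM) != 1L || !is.finite(cmaxUM) ||
      cmaxUM <= 0)
    stop("cmaxUM must be a single positive concentration in uM")
  r <- -log10(cmaxUM * 1.5) + 6
  s <- -log10(cmaxUM / 1.5) + 6
  if (!is.null(clampFloor)) {
    r <- max(r, clampFloor)
    s <- max(s, clampFloor)
  }
  new("CutoffPair", resistant = r, sensitive = s, source = "clinical",
      cmaxUM = cmaxUM, muUM = numeric(), sigmaUM = numeric())
}

#' Statistical resistant/sensitive cutoffs from the EC50 distribution
#'
#' For drugs without a reliable clinical Cmax, the cutoffs are anchored on
#' the EC50 distribution across cell lines: with \eqn{\mu} and \eqn{\sigma}
#' the mean and SD of the EC50 values (uM),
#' \deqn{resistant = -log10((\mu + 0.3\sigma) 10^{-6}), \quad
#'       sensitive = -log10((\mu - 0.3\sigma) 10^{-6}).}
#' Because \code{-log10} is decreasing, resistant <= sensitive always
#' holds. Sample SD (n-1 denominator) is used by default.
#'
#' @param ec50UM numeric vector of EC50 values in uM, length >= 2.
#' @param sdType \code{"sample"} (n-1, default) or \code{"population"} (n).
#' @return a \code{\linkS4class{CutoffPair}}.
#' @examples
#' statisticalCutoffs(c(1, 1, 3, 3))  # 5.630 / 5.782
#' @export
statisticalCutoffs <- function(ec50UM, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (!is.numeric(ec50UM) || length(ec50UM) < 2L)
    stop("need at least 2 EC50 values")
  if (any(!is.finite(ec50UM)) || any(ec50UM <= 0))
    stop("EC50 values must be finite and strictly positive")
  mu <- mean(ec50UM)
  sigma <- sd(ec50UM)
  if (sdType == "population")
    sigma <- sigma * sqrt((length(ec50UM) - 1) / length(ec50UM))
  lo <- mu - 0.3 * sigma
  if (lo <= 0)
    stop("statistical cutoff undefined: mu - 0.3*sigma <= 0")
  new("CutoffPair",
      resistant = -log10((mu + 0.3 * sigma) * 1e-6),
      sensitive = -log10(lo * 1e-6),
      source = "statistical",
      cmaxUM = numeric(), muUM = mu, sigmaUM = sigma)
}

#' Assign resistant / ambiguous / sensitive labels
#'
#' Scores each cell line as \code{-log10(EC50 [M])} and compares it with
#' the cutoff pair using strict inequalities: strictly above the sensitive
#' cutoff is sensitive, strictly below the resistant cutoff is resistant,
#' anything in between -- including a score exactly equal to a cutoff -- is
#' ambiguous.
#'
#' @param ec50UM numeric vector of EC50 values in uM, strictly positive.
#' @param cutoffs a \code{\linkS4class{CutoffPair}}.
#' @return factor with levels \code{resistant}, \code{ambiguous},
#'   \code{sensitive}, named like the input.
#' @export
assignLabels <- function(ec50UM, cutoffs) {
  stopifnot(is(cutoffs, "CutoffPair"))
  if (any(!is.finite(ec50UM)) || any(ec50UM <= 0))
    stop("EC50 values must be finite and strictly positive")
  score <- -log10(ec50UM * 1e-6)
  lab <- ifelse(score > cutoffs@sensitive, "sensitive",
         ifelse(score < cutoffs@resistant, "resistant", "ambiguous"))
  factor(setNames(lab, names(ec50UM)),
         levels = c("resistant", "ambiguous", "sensitive"))
}

#' Drop ambiguous cell lines and build a two-class labeled dataset
#'
#' Removes cell lines in the ambiguous zone (they belong to neither class
#' and are excluded from training and testing) and returns the remaining
#' two-class dataset.
#'
#' @param expr expression matrix, genes x cell lines.
#' @param labels factor from \code{\link{assignLabels}} aligned to the
#'   columns of \code{expr}.
#' @return list with \code{expr} (ambiguous columns removed), \code{labels}
#'   (factor with levels resistant/sensitive) and \code{droppedAmbiguous}
#'   (count).
#' @export
dropAmbiguous <- function(expr, labels) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  keep <- labels != "ambiguous"
  out <- list(
    expr = expr[, keep, drop = FALSE],
    labels = factor(as.character(labels[keep]),
                    levels = c("resistant", "sensitive")),
    droppedAmbiguous = sum(!keep)
  )
  if (!all(c("resistant", "sensitive") %in% out$labels))
    warning("one of the two classes is empty after dropping ambiguous cell lines")
  out
}

#' Retain drugs with enough cell lines in both classes
#'
#' A drug whose resistant/sensitive distribution is strongly biased toward
#' one class cannot support model training; such drugs are excluded. A drug
#' is retained iff both classes have at least \code{minPerClass}
#' non-ambiguous cell lines.
#'
#' @param labelSets named list of label factors (one per drug), as produced
#'   by \code{\link{assignLabels}}.
#' @param minPerClass minimum per-class count, >= 1.
#' @return character vector of retained drug names.
#' @export
filterBalancedDrugs <- function(labelSets, minPerClass) {
  stopifnot(minPerClass >= 1)
  keep <- vapply(labelSets, function(lab) {
    sum(lab == "resistant") >= minPerClass &&
      sum(lab == "sensitive") >= minPerClass
  }, logical(1))
  names(labelSets)[keep]
}
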