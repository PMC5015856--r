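#' Two-by-three confusion matrix with an ambiguous column
#'
#' Counts for actual sensitive / resistant samples against predicted
#' sensitive / ambiguous / resistant. Regression-style predictors can place
#' a predicted response value between the two cutoffs (predicted
#' ambiguous); classifiers never do, so \code{fas = far = 0} for them.
#'
#' @param ts true sensitive (actual sensitive, predicted sensitive).
#' @param fas false ambiguous from sensitive.
#' @param fr false resistant (actual sensitive, predicted resistant).
#' @param fs false sensitive (actual resistant, predicted sensitive).
#' @param far false ambiguous from resistant.
#' @param tr true resistant.
#' @return named numeric vector of class \code{confusionMatrix23}.
#' @export
confusionMatrix23 <- function(ts = 0, fas = 0, fr = 0, fs = 0, far = 0,
                              tr = 0) {
  cm <- c(ts = ts, fas = fas, fr = fr, fs = fs, far = far, tr = tr)
  if (any(cm < 0)) stop("confusion counts must be non-negative")
  structure(cm, class = "confusionMatrix23")
}

# tabulate actual two-class labels vs three-way predictions
tabulateConfusion <- function(actual, predicted) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  stopifnot(length(actual) == length(predicted),
            all(actual %in% c("resistant", "sensitive")),
            all(predicted %in% c("resistant", "ambiguous", "sensitive")))
  confusionMatrix23(
    ts  = sum(actual == "sensitive" & predicted == "sensitive"),
    fas = sum(actual == "sensitive" & predicted == "ambiguous"),
    fr  = sum(actual == "sensitive" & predicted == "resistant"),
    fs  = sum(actual == "resistant" & predicted == "sensitive"),
    far = sum(actual == "resistant" & predicted == "ambiguous"),
    tr  = sum(actual == "resistant" & predicted == "resistant"))
}

#' Balanced accuracy over a 2 x 3 confusion matrix
#'
#' \deqn{0.5 \frac{TS}{TS+FAS+FR} + 0.5 \frac{TR}{FS+FAR+TR}}
#' With no ambiguous predictions this is the ordinary balanced accuracy
#' (mean per-class recall); with them, samples predicted ambiguous count
#' against their actual class, extending the metric to regression-style
#' predictors.
#'
#' @param cm a \code{\link{confusionMatrix23}}.
#' @return value in [0, 1].
#' @export
balancedAccuracy <- function(cm) {
  rs <- cm["ts"] + cm["fas"] + cm["fr"]
  rr <- cm["fs"] + cm["far"] + cm["tr"]
  if (rs == 0 || rr == 0)
    stop("metric error: an actual class is empty")
  unname(0.5 * cm["ts"] / rs + 0.5 * cm["tr"] / rr)
}

#' Balanced rate of falling into the ambiguous zone
#'
#' \deqn{0.5 \frac{FAS}{TS+FAS+FR} + 0.5 \frac{FAR}{FS+FAR+TR}}
#' Zero for classifiers, which never predict ambiguous. Together with the
#' balanced accuracy and the balanced error rate this partitions each
#' actual class (the three rates sum to exactly 1).
#'
#' @param cm a \code{\link{confusionMatrix23}}.
#' @return value in [0, 1].
#' @export
ambiguousRate <- function(cm) {
  rs <- cm["ts"] + cm["fas"] + cm["fr"]
  rr <- cm["fs"] + cm["far"] + cm["tr"]
  if (rs == 0 || rr == 0)
    stop("metric error: an actual class is empty")
  unname(0.5 * cm["fas"] / rs + 0.5 * cm["far"] / rr)
}

#' Matthews correlation coefficient
#'
#' Standard binary MCC on the 2 x 2 part of the confusion matrix,
#' \deqn{\frac{TS \cdot TR - FS \cdot FR}
#'       {\sqrt{(TS+FS)(TS+FR)(TR+FS)(TR+FR)}},}
#' defined as 0 when any factor in the denominator is 0. Ambiguous counts
#' are dropped with a warning (the metric is defined for classifiers).
#'
#' @param cm a \code{\link{confusionMatrix23}}.
#' @return value in [-1, 1].
#' @export
mcc <- function(cm) {
  if (cm["fas"] > 0 || cm["far"] > 0)
    warning("MCC is computed on the 2x2 part; ambiguous counts dropped")
  ts <- cm["ts"]; tr <- cm["tr"]; fs <- cm["fs"]; fr <- cm["fr"]
  den <- (ts + fs) * (ts + fr) * (tr + fs) * (tr + fr)
  if (den == 0) return(0)
  unname((ts * tr - fs * fr) / sqrt(den))
}

#' Area under the ROC curve of a decision score
#'
#' AUC of \code{scores} for separating sensitive from resistant samples,
#' with larger scores favouring sensitive. For the two-network classifier
#' the canonical decision score is \code{mseResistant - mseSensitive}, the
#' margin of the MSE rule. Computed by the rank (Mann-Whitney) method via
#' \pkg{pROC}; ties contribute 0.5.
#'
#' @param scores numeric decision values, one per sample.
#' @param labels factor/character with both classes \code{resistant} and
#'   \code{sensitive} present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("resistant", "sensitive")))
  if (length(unique(labels)) < 2L)
    stop("metric error: both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c("resistant", "sensitive"),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}
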