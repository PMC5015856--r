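#' Default run configuration
#'
#' A flat named list of every pipeline setting with its default. The
#' correlation-threshold grid, ridge penalty and SVR-RBF search grid carry
#' the standard parameter spaces used in published evaluations of this
#' classifier family. Unknown keys in a user configuration are rejected
#' fail-closed.
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    outputDir = "nbc_out",
    overwrite = FALSE,
    dialect = "tsv",
    expressionFile = NULL,
    responseFile = NULL,
    labelsFile = NULL,
    modelFile = NULL,
    drug = NULL,
    # labeling
    cutoffSource = "clinical",  # or "statistical"
    cmaxUM = NULL,
    clampFloor = 5,
    sdType = "sample",
    minPerClass = 5,
    # feature selection
    featureMethod = "chi2",     # chi2 | random
    geneListFile = NULL,
    nFeatures = 100L,
    tBins = 10L,
    # model
    predictor = "ridge",        # ridge | svr
    corrThreshold = 0.76,
    corrGrid = seq(0.4, 0.94, by = 0.06),
    lambda = 1e-3,
    svrC = c(0.1, 1, 10),
    svrGamma = c(0.1, 1, 10),
    svrEpsilon = 0.1,
    svrFolds = 5L,
    # evaluation protocol
    outerFolds = 5L,
    innerFolds = 5L,
    nRepeats = 10L,
    # synthetic generator
    synNGenes = 60L,
    synNPerClass = 100L,
    synNBlocks = 6L,
    synWithinBlockCorr = 0.9,
    synDivergence = 1,
    synEc50Separation = 2,
    synEc50Sd = 0.5
  )
}

#' Validate and complete a run configuration
#'
#' Merges user settings over \code{\link{defaultConfig}}; any key not in
#' the default set is a configuration error (fail-closed), as are
#' out-of-range values for the settings that have hard domains.
#'
#' @param config named list of user settings (possibly from a YAML file).
#' @return completed configuration list.
#' @export
validateConfig <- function(config = list()) {
  defaults <- defaultConfig()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  if (!cfg$predictor %in% c("ridge", "svr"))
    stop("configuration error: predictor must be 'ridge' or 'svr'")
  if (!cfg$cutoffSource %in% c("clinical", "statistical"))
    stop("configuration error: cutoffSource must be 'clinical' or 'statistical'")
  if (!cfg$featureMethod %in% c("chi2", "random"))
    stop("configuration error: featureMethod must be 'chi2' or 'random'")
  if (cfg$corrThreshold <= 0 || cfg$corrThreshold >= 1)
    stop("configuration error: corrThreshold must lie strictly in (0, 1)")
  if (any(cfg$corrGrid <= 0) || any(cfg$corrGrid >= 1))
    stop("configuration error: corrGrid values must lie strictly in (0, 1)")
  if (cfg$lambda <= 0)
    stop("configuration error: lambda must be positive")
  if (cfg$nFeatures < 1 || cfg$tBins < 2)
    stop("configuration error: nFeatures >= 1 and tBins >= 2 required")
  cfg
}

readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

prepareOutputDir <- function(cfg) {
  dir <- cfg$outputDir
  if (dir.exists(dir) && !cfg$overwrite &&
      length(list.files(dir)) > 0L)
    stop("output directory ", dir,
         " is non-empty; set overwrite: true to reuse it")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # echo the effective configuration for provenance
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "config_used.yaml"))
  dir
}

cutoffsFromConfig <- function(cfg, ec50) {
  if (cfg$cutoffSource == "clinical") {
    if (is.null(cfg$cmaxUM))
      stop("configuration error: clinical cutoffs need cmaxUM")
    clinicalCutoffs(cfg$cmaxUM, clampFloor = cfg$clampFloor)
  } else {
    statisticalCutoffs(ec50, sdType = cfg$sdType)
  }
}

loadLabeledDataset <- function(cfg) {
  expr <- readExpressionMatrix(cfg$expressionFile, dialect = cfg$dialect)
  resp <- readDrugResponse(cfg$responseFile)
  if (is.null(cfg$drug)) stop("configuration error: drug is required")
  al <- alignDataset(expr, resp, cfg$drug)
  cutoffs <- cutoffsFromConfig(cfg, al$ec50)
  labels3 <- assignLabels(al$ec50, cutoffs)
  ds <- dropAmbiguous(al$expr, labels3)
  ds$cutoffs <- cutoffs
  ds
}

predictorFromConfig <- function(cfg, tuneGrid = TRUE) {
  candidates <- if (!is.null(cfg$geneListFile)) readGeneList(cfg$geneListFile)
  nbcPredictor(
    predictor = cfg$predictor, nFeatures = cfg$nFeatures, tBins = cfg$tBins,
    lambda = cfg$lambda,
    corrGrid = if (tuneGrid) cfg$corrGrid else cfg$corrThreshold,
    svrGrid = list(C = cfg$svrC, gamma = cfg$svrGamma,
                   epsilon = cfg$svrEpsilon),
    svrFolds = cfg$svrFolds, candidates = candidates,
    featureMethod = cfg$featureMethod)
}

#' Run one pipeline command
#'
#' Thin driver behind the command-line interface. Commands:
#' \describe{
#'   \item{synth}{generate a synthetic dataset and write expression (tsv),
#'     response (csv) and true labels (csv) into \code{outputDir}.}
#'   \item{label}{compute cutoffs for \code{drug} and write the three-zone
#'     label assignment.}
#'   \item{train}{align, label, drop ambiguous cell lines, train an NBC
#'     model at \code{corrThreshold} and save it.}
#'   \item{predict}{classify the cell lines of an expression matrix with a
#'     saved model.}
#'   \item{evaluate}{repeated double nested stratified cross-validation;
#'     writes a metrics TSV and JSON.}
#'   \item{contribution}{per-gene prediction success rates of a saved model
#'     on a labeled dataset.}
#' }
#' The effective configuration is echoed into \code{outputDir} as
#' \code{config_used.yaml}; identical configurations produce identical
#' outputs.
#'
#' @param command one of the commands above.
#' @param config named list of settings or path to a YAML file; validated
#'   against \code{\link{defaultConfig}}.
#' @return invisibly, a named list of the artifact paths written.
#' @export
runPipeline <- function(command = c("synth", "label", "train", "predict",
                                    "evaluate", "contribution"),
                        config = list()) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L)
    config <- readConfigFile(config)
  cfg <- validateConfig(config)
  dir <- prepareOutputDir(cfg)
  paths <- list(config = file.path(dir, "config_used.yaml"))

  if (command == "synth") {
    spec <- syntheticSpec(
      nGenes = cfg$synNGenes, nPerClass = cfg$synNPerClass,
      nBlocks = cfg$synNBlocks, withinBlockCorr = cfg$synWithinBlockCorr,
      blockAssignmentDivergence = cfg$synDivergence,
      ec50Separation = cfg$synEc50Separation, ec50Sd = cfg$synEc50Sd,
      seed = cfg$seed)
    ds <- generateDataset(spec)
    paths$expression <- file.path(dir, "expression.tsv")
    paths$response <- file.path(dir, "response.csv")
    paths$labels <- file.path(dir, "true_labels.csv")
    writeExpressionMatrix(ds$expr, paths$expression)
    write.table(ds$response, paths$response, sep = ",", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(cell_line = names(ds$labels),
                           label = as.character(ds$labels)),
                paths$labels, sep = ",", quote = FALSE, row.names = FALSE)
  } else if (command == "label") {
    resp <- readDrugResponse(cfg$responseFile)
    rec <- resp[resp$drug == cfg$drug, , drop = FALSE]
    if (!nrow(rec)) stop("no response records for drug '", cfg$drug, "'")
    ec50 <- setNames(rec$ec50_um, rec$cell_line)
    cutoffs <- cutoffsFromConfig(cfg, ec50)
    lab <- assignLabels(ec50, cutoffs)
    paths$labels <- file.path(dir, "labels.csv")
    write.table(data.frame(cell_line = names(lab),
                           label = as.character(lab),
                           resistant_cutoff = resistantCutoff(cutoffs),
                           sensitive_cutoff = sensitiveCutoff(cutoffs)),
                paths$labels, sep = ",", quote = FALSE, row.names = FALSE)
  } else if (command == "train") {
    ds <- loadLabeledDataset(cfg)
    candidates <- if (!is.null(cfg$geneListFile)) readGeneList(cfg$geneListFile)
    model <- nbcTrain(
      ds$expr, ds$labels, corrThreshold = cfg$corrThreshold,
      predictor = cfg$predictor, nFeatures = cfg$nFeatures,
      tBins = cfg$tBins, lambda = cfg$lambda,
      svrGrid = list(C = cfg$svrC, gamma = cfg$svrGamma,
                     epsilon = cfg$svrEpsilon),
      svrFolds = cfg$svrFolds, candidates = candidates, seed = cfg$seed)
    paths$model <- file.path(dir, "model.rds")
    saveNBCModel(model, paths$model)
  } else if (command == "predict") {
    if (is.null(cfg$modelFile)) stop("configuration error: modelFile is required")
    model <- readNBCModel(cfg$modelFile)
    expr <- readExpressionMatrix(cfg$expressionFile, dialect = cfg$dialect)
    pred <- classifyMatrix(model, expr)
    paths$predictions <- file.path(dir, "predictions.csv")
    write.table(pred, paths$predictions, sep = ",", quote = FALSE,
                row.names = FALSE)
  } else if (command == "evaluate") {
    ds <- loadLabeledDataset(cfg)
    report <- nestedCV(ds$expr, ds$labels, predictorFromConfig(cfg),
                       outerFolds = cfg$outerFolds,
                       innerFolds = cfg$innerFolds,
                       nRepeats = cfg$nRepeats, seed = cfg$seed)
    paths$metricsTsv <- file.path(dir, "metrics.tsv")
    tsv <- data.frame(
      drug = cfg$drug, predictor = report$predictor,
      metric = c("bac", "mcc", "ambiguous_rate", "auc"),
      mean = c(report$bac, report$mcc, report$ambiguousRate, report$auc),
      sd = c(report$bacSd, report$mccSd, NA, NA),
      n_repeats = cfg$nRepeats, seed = cfg$seed)
    write.table(tsv, paths$metricsTsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$metricsJson <- file.path(dir, "metrics.json")
    jsonlite::write_json(
      report[c("predictor", "bac", "bacSd", "mcc", "mccSd",
               "ambiguousRate", "auc", "outerFolds", "innerFolds",
               "nRepeats", "seed")],
      paths$metricsJson, auto_unbox = TRUE, digits = NA)
  } else if (command == "contribution") {
    if (is.null(cfg$modelFile)) stop("configuration error: modelFile is required")
    model <- readNBCModel(cfg$modelFile)
    ds <- loadLabeledDataset(cfg)
    profile <- predictionSuccessRate(model, ds$expr, ds$labels)
    paths$contribution <- file.path(dir, "prediction_success_rate.tsv")
    write.table(profile, paths$contribution, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
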