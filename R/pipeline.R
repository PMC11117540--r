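#' @include evaluation.R features.R mspca.R data_io.R
NULL

.PIPELINE_SCHEMA <- list(
  seed = NULL,
  logLevel = NULL,
  io = c("epochLen", "artifactThresholdUv", "channel", "fs"),
  input = c("files", "labels"),
  synthetic = c("enabled", "nTrialsPerClass", "epochLen", "fs",
                "normalAmplitudes", "alcoholicAmplitudes", "arCoeff",
                "noiseSd", "spikeRate", "spikeAmplitude"),
  mspca = c("enabled", "levels", "finalPca"),
  frft = c("alpha", "chirp"),
  selection = c("k", "weights", "mode", "where"),
  classifier = c("kind", "learningRate", "hiddenUnits", "activation",
                 "epochs", "sigma", "radius"),
  evaluation = c("folds")
)

#' Pipeline configuration
#'
#' Builds (and validates) the nested configuration for [runPipeline()].
#' Defaults reproduce the reference workflow settings: Symlet-4 wavelet
#' with 5 levels, 2048-sample epochs, a 73.3 microvolt artifact
#' threshold, transform order 0.5, K = 16 selected features, and the
#' per-architecture classifier defaults of [classifierConfig()]. Unknown
#' keys are rejected by name.
#'
#' @param ... named sections overriding the defaults; each section is a
#'   named list (sections: \code{io}, \code{input}, \code{synthetic},
#'   \code{mspca}, \code{frft}, \code{selection}, \code{classifier},
#'   \code{evaluation}) plus the top-level scalars \code{seed} and
#'   \code{logLevel}.
#' @param file optional YAML file whose contents are merged before
#'   \code{...} overrides.
#' @return Nested list of class \code{"pipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(synthetic = list(nTrialsPerClass = 10),
#'                       classifier = list(kind = "grnn"))
#' @export
pipelineConfig <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    logLevel = "info",
    io = list(epochLen = 2048L, artifactThresholdUv = 73.3,
              channel = 1L, fs = 256),
    input = list(files = character(), labels = character()),
    synthetic = list(enabled = TRUE, nTrialsPerClass = 120L,
                     epochLen = 2048L, fs = 256,
                     normalAmplitudes = NULL, alcoholicAmplitudes = NULL,
                     arCoeff = 0.85, noiseSd = 3, spikeRate = 0,
                     spikeAmplitude = 200),
    mspca = list(enabled = TRUE, levels = 5L, finalPca = TRUE),
    frft = list(alpha = 0.5, chirp = "auto"),
    selection = list(k = 16L, weights = rep(1, 5), mode = "ensemble",
                     where = "fold"),
    classifier = list(kind = "rnn", learningRate = NULL,
                      hiddenUnits = NULL, activation = NULL,
                      epochs = NULL, sigma = 0.5, radius = 0.1),
    evaluation = list(folds = 10L)
  )
  user <- list(...)
  if (!is.null(file)) {
    fromFile <- yaml::read_yaml(file)
    user <- utils::modifyList(fromFile, user)
  }
  for (sec in names(user)) {
    if (!sec %in% names(.PIPELINE_SCHEMA))
      stop("unknown config section: '", sec, "'")
    allowed <- .PIPELINE_SCHEMA[[sec]]
    if (is.null(allowed)) {           # scalar key
      defaults[[sec]] <- user[[sec]]
      next
    }
    if (!is.list(user[[sec]]))
      stop("config section '", sec, "' must be a named list")
    bad <- setdiff(names(user[[sec]]), allowed)
    if (length(bad))
      stop("unknown config key: '", sec, ".", bad[1], "'")
    defaults[[sec]] <- utils::modifyList(defaults[[sec]], user[[sec]],
                                         keep.null = TRUE)
  }
  structure(defaults, class = "pipelineConfig")
}

## stable per-stage seed derived from the master seed and the stage name
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  (as.integer(seed) * 7919L + h) %% .Machine$integer.max
}

.logStage <- function(cfg, ...) {
  if (identical(cfg$logLevel, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [frfteeg] ", ...)
}

#' Run the full detection pipeline
#'
#' Executes the complete workflow: obtain labelled epochs (from the
#' synthetic generator, or from UCI-style trial files that are MSPCA
#' denoised and segmented), apply the amplitude artifact rule, transform
#' every epoch with the fast FrFT, extract the 34 graphical features,
#' select features, and evaluate the configured classifier with
#' stratified cross-validation. Cross-channel MSPCA denoising applies to
#' multichannel recordings; independently generated synthetic trials are
#' not simultaneous channels, so the denoising stage is skipped for them.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional directory; when given, writes
#'   \code{features.csv}, \code{selection.json} and \code{report.json}.
#' @return A list with elements \code{features} ([FeatureSet-class]),
#'   \code{selection} ([SelectionResult-class]), \code{report}
#'   ([CVReport-class]) and \code{config}.
#' @examples
#' cfg <- pipelineConfig(synthetic = list(nTrialsPerClass = 6,
#'                                        epochLen = 256),
#'                       classifier = list(kind = "grnn"),
#'                       evaluation = list(folds = 3), logLevel = "quiet")
#' res <- runPipeline(cfg)
#' res$report
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  seed <- config$seed
  if (length(config$input$files)) {
    .logStage(config, "reading ", length(config$input$files),
              " trial file(s)")
    epochList <- lapply(seq_along(config$input$files), function(i) {
      rec <- readUciTrial(config$input$files[i], fs = config$io$fs,
                          subjectClass = config$input$labels[i])
      if (isTRUE(config$mspca$enabled) && nChannels(rec) >= 2L) {
        rec <- denoiseRecording(rec, levels = config$mspca$levels,
                                finalPca = config$mspca$finalPca)
      }
      segmentEpochs(rec, epochLen = config$io$epochLen)
    })
    epochs <- do.call(.bindEpochSets, epochList)
  } else if (isTRUE(config$synthetic$enabled)) {
    .logStage(config, "generating synthetic dataset")
    args <- config$synthetic
    args$enabled <- NULL
    args <- Filter(Negate(is.null), args)
    scfg <- do.call(synthConfig,
                    c(args, list(seed = .stageSeed(seed, "synthetic"))))
    epochs <- generateDataset(scfg)
  } else {
    stop("stage input: no input files and synthetic generation disabled")
  }
  .logStage(config, "artifact screening at ",
            config$io$artifactThresholdUv, " uV")
  epochs <- dropArtifacts(
    flagArtifacts(epochs, threshold = config$io$artifactThresholdUv))
  if (length(epochs) == 0L) stop("stage artifacts: all epochs flagged")
  .logStage(config, "FrFT + feature extraction on ", length(epochs),
            " epochs")
  feats <- epochFeatures(epochs, alpha = config$frft$alpha,
                         chirp = config$frft$chirp)
  .logStage(config, "ensemble feature selection (k = ",
            config$selection$k, ")")
  sel <- ensembleSelect(feats, k = config$selection$k,
                        weights = config$selection$weights,
                        mode = config$selection$mode)
  .logStage(config, "cross-validated evaluation")
  clsArgs <- Filter(Negate(is.null), config$classifier)
  ccfg <- do.call(classifierConfig,
                  c(clsArgs, list(seed = .stageSeed(seed, "classifier"))))
  report <- runCV(feats, config = ccfg, k = config$evaluation$folds,
                  seed = .stageSeed(seed, "folds"),
                  selection = config$selection$where,
                  nSelect = config$selection$k,
                  selectionMode = config$selection$mode)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureMatrix(feats, file.path(outDir, "features.csv"))
    jsonlite::write_json(
      list(perScorer = scorerScores(sel),
           ensemble = as.numeric(ensembleScores(sel)),
           selected = selectedFeatures(sel),
           names = sel@featureNames[selectedFeatures(sel)]),
      file.path(outDir, "selection.json"), digits = NA, auto_unbox = TRUE)
    jsonlite::write_json(
      list(folds = lapply(cvFolds(report), as.list),
           meanMetrics = as.list(cvMetrics(report)),
           foldSizes = report@foldSizes),
      file.path(outDir, "report.json"), digits = NA, auto_unbox = TRUE)
    .logStage(config, "artifacts written to ", outDir)
  }
  list(features = feats, selection = sel, report = report,
       config = config)
}

## row-bind several EpochSets
.bindEpochSets <- function(...) {
  sets <- list(...)
  new("EpochSet",
      samples = do.call(rbind, lapply(sets, function(s) s@samples)),
      channel = unlist(lapply(sets, function(s) s@channel)),
      label = unlist(lapply(sets, function(s) s@label)),
      artifactFlag = unlist(lapply(sets, function(s) s@artifactFlag)))
}
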