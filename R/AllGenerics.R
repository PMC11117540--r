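#' @include AllClasses.R
NULL

#' Accessors for frfteeg classes
#'
#' Small accessor generics for the package's S4 containers. Slot access
#' via \code{@} is discouraged; these are the supported interface.
#'
#' @param x an frfteeg S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("subjectClass", function(x) standardGeneric("subjectClass"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("artifactFlags", function(x) standardGeneric("artifactFlags"))
#' @rdname accessors
#' @export
setGeneric("frftCoefficients", function(x) standardGeneric("frftCoefficients"))
#' @rdname accessors
#' @export
setGeneric("scatterPoints", function(x) standardGeneric("scatterPoints"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("ensembleScores", function(x) standardGeneric("ensembleScores"))
#' @rdname accessors
#' @export
setGeneric("scorerScores", function(x) standardGeneric("scorerScores"))
#' @rdname accessors
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))
#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

## ---- EEGRecording ----

#' @rdname accessors
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@samples))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("subjectClass", "EEGRecording", function(x) x@subjectClass)
#' @rdname accessors
#' @export
setMethod("signalMatrix", "EEGRecording", function(x) {
  m <- x@samples
  rownames(m) <- x@channelLabels
  m
})

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@samples), "channel(s) x",
      ncol(object@samples), "samples @", object@fs, "Hz\n")
  cat("  class:", object@subjectClass, "\n")
  cat("  channels:", paste(head(object@channelLabels, 6), collapse = ", "),
      if (length(object@channelLabels) > 6) "...", "\n")
})

#' Number of epochs / samples
#'
#' \code{length} of an \code{EpochSet} is its number of epochs.
#' @param x an \code{EpochSet}.
#' @export
setMethod("length", "EpochSet", function(x) nrow(x@samples))

## ---- EpochSet ----

#' @rdname accessors
#' @export
setMethod("signalMatrix", "EpochSet", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("epochLabels", "EpochSet", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channel)
#' @rdname accessors
#' @export
setMethod("artifactFlags", "EpochSet", function(x) x@artifactFlag)

#' Subset an EpochSet
#'
#' @param x an \code{EpochSet}.
#' @param i epoch indices (integer or logical).
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochSet", samples = x@samples[i, , drop = FALSE],
      channel = x@channel[i], label = x@label[i],
      artifactFlag = x@artifactFlag[i])
})

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", nrow(object@samples), "epoch(s) x",
      ncol(object@samples), "samples\n")
  tab <- table(factor(object@label, levels = .CLASS_LEVELS))
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  flagged artifacts:", sum(object@artifactFlag), "\n")
})

## ---- FrFTScatter ----

#' @rdname accessors
#' @export
setMethod("frftCoefficients", "FrFTScatter", function(x) x@coefficients)

#' @rdname accessors
#' @export
setMethod("scatterPoints", "FrFTScatter", function(x) {
  cbind(x = Re(x@coefficients), y = Im(x@coefficients))
})

#' @rdname accessors
#' @export
setMethod("length", "FrFTScatter", function(x) length(x@coefficients))

setMethod("show", "FrFTScatter", function(object) {
  cat("FrFTScatter: N =", length(object@coefficients),
      " alpha =", object@alpha, " chirp =", object@chirp, "\n")
})

## ---- FeatureSet ----

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureSet", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("epochLabels", "FeatureSet", function(x) x@labels)

#' @rdname accessors
#' @param i row (epoch) indices.
#' @param j column (feature) indices.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "FeatureSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  new("FeatureSet", values = x@values[i, j, drop = FALSE],
      labels = x@labels[i], featureNames = x@featureNames[j])
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", nrow(object@values), "epoch(s) x",
      ncol(object@values), "feature(s)\n")
  tab <- table(factor(object@labels, levels = .CLASS_LEVELS))
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

## ---- SelectionResult ----

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)
#' @rdname accessors
#' @export
setMethod("ensembleScores", "SelectionResult", function(x) {
  setNames(x@ensemble, x@featureNames)
})
#' @rdname accessors
#' @export
setMethod("scorerScores", "SelectionResult", function(x) x@perScorer)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@selected), "of",
      ncol(object@perScorer), "features selected\n")
  cat("  selected:",
      paste(object@featureNames[object@selected], collapse = ", "), "\n")
})

## ---- NeuralModel / CVReport ----

setMethod("show", "NeuralModel", function(object) {
  cat("NeuralModel:", object@kind, " input dim:", object@inputDim, "\n")
  if (length(object@trainHistory))
    cat("  final training loss:",
        signif(object@trainHistory[length(object@trainHistory)], 5), "\n")
})

#' @rdname accessors
#' @export
setMethod("cvFolds", "CVReport", function(x) x@folds)
#' @rdname accessors
#' @export
setMethod("cvMetrics", "CVReport", function(x) x@meanMetrics)

setMethod("show", "CVReport", function(object) {
  cat("CVReport:", length(object@folds), "folds (train",
      object@foldSizes[1], "/ test", object@foldSizes[2], ")\n")
  m <- object@meanMetrics
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  cat(sprintf("  precision %.1f%%  F1 %.1f%%  kappa %.3f\n",
              m["precision"], m["f1"], m["kappa"]))
})
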