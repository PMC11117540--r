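#' @include frfteeg-package.R
NULL

.CLASS_LEVELS <- c("normal", "alcoholic")

#' EEGRecording: a multichannel EEG recording
#'
#' Container for a raw multichannel EEG recording in microvolts. Rows are
#' channels, columns are time samples at a common sampling rate.
#'
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot channelLabels character vector, one label per channel row.
#' @slot fs sampling rate in Hz (default 256).
#' @slot subjectClass one of \code{"normal"}, \code{"alcoholic"},
#'   \code{"unknown"}.
#'
#' @seealso [EEGRecording()], [segmentEpochs()], [mspcaDenoise()]
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    samples = "matrix",
    channelLabels = "character",
    fs = "numeric",
    subjectClass = "character"
  ),
  prototype(fs = 256, subjectClass = "unknown")
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite with no NA")
  if (length(object@channelLabels) != nrow(object@samples))
    msg <- c(msg, "one channel label per sample row required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!object@subjectClass %in% c(.CLASS_LEVELS, "unknown"))
    msg <- c(msg, "subjectClass must be 'normal', 'alcoholic' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples numeric matrix (channels x time) or a vector for a
#'   single channel, in microvolts.
#' @param channelLabels channel names; defaults to \code{ch1, ch2, ...}.
#' @param fs sampling rate in Hz.
#' @param subjectClass class label of the subject the recording came from.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), nrow = 2), fs = 256)
#' nChannels(rec)
#' @export
EEGRecording <- function(samples, channelLabels = NULL, fs = 256,
                         subjectClass = c("unknown", "normal", "alcoholic")) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  subjectClass <- match.arg(subjectClass)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(samples)))
  new("EEGRecording", samples = samples, channelLabels = channelLabels,
      fs = as.numeric(fs), subjectClass = subjectClass)
}

#' EpochSet: fixed-length labelled EEG epochs
#'
#' Epochs are stored row-wise in a single matrix: each row holds one
#' epoch of \code{ncol(samples)} consecutive samples from one channel.
#' Artifact flags mark epochs whose absolute amplitude exceeded the
#' screening threshold.
#'
#' @slot samples numeric matrix, epochs x epoch length, microvolts.
#' @slot channel source channel label per epoch.
#' @slot label class label per epoch ("normal"/"alcoholic").
#' @slot artifactFlag logical per epoch; TRUE when the amplitude rule fired.
#'
#' @seealso [segmentEpochs()], [flagArtifacts()], [dropArtifacts()]
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    samples = "matrix",
    channel = "character",
    label = "character",
    artifactFlag = "logical"
  )
)

setValidity("EpochSet", function(object) {
  n <- nrow(object@samples)
  msg <- character()
  if (length(object@channel) != n) msg <- c(msg, "channel length != epochs")
  if (length(object@label) != n) msg <- c(msg, "label length != epochs")
  if (length(object@artifactFlag) != n)
    msg <- c(msg, "artifactFlag length != epochs")
  if (!all(object@label %in% .CLASS_LEVELS))
    msg <- c(msg, "labels must be 'normal' or 'alcoholic'")
  if (anyNA(object@samples)) msg <- c(msg, "epoch samples contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param samples numeric matrix, one epoch per row (microvolts).
#' @param label class label(s), recycled to the number of epochs.
#' @param channel source channel label(s), recycled likewise.
#' @param artifactFlag logical flags, default all FALSE.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(samples, label, channel = "ch1",
                     artifactFlag = FALSE) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  n <- nrow(samples)
  new("EpochSet", samples = samples,
      channel = rep_len(as.character(channel), n),
      label = rep_len(as.character(label), n),
      artifactFlag = rep_len(as.logical(artifactFlag), n))
}

#' FrFTScatter: fast fractional Fourier coefficients of one epoch
#'
#' Ordered complex coefficients \eqn{c_k}, \eqn{k = 0..N-1}, of the
#' stage-filtered fast FrFT, plus the stage-filtered signal they were
#' computed from. The 2D scatter used for feature extraction is the
#' ordered sequence of points \eqn{(Re\,c_k, Im\,c_k)}.
#'
#' @slot alpha fractional transform order (unitless).
#' @slot coefficients complex vector of length N (a power of two).
#' @slot yFiltered complex vector: the signal after the stage-filter loop.
#' @slot chirp kernel convention used: \code{"complex"} (the complex-valued
#'   chirp exponent) or \code{"real"} (pure-phase chirp, usable at any N).
#'
#' @seealso [fastFrFT()], [scatterPoints()]
#' @exportClass FrFTScatter
setClass("FrFTScatter",
  representation(
    alpha = "numeric",
    coefficients = "complex",
    yFiltered = "complex",
    chirp = "character"
  )
)

setValidity("FrFTScatter", function(object) {
  n <- length(object@coefficients)
  msg <- character()
  if (n < 1L || bitwAnd(n, n - 1L) != 0L)
    msg <- c(msg, "coefficient length must be a power of two")
  if (length(object@yFiltered) != n)
    msg <- c(msg, "yFiltered must match coefficient length")
  if (length(object@alpha) != 1L || !is.finite(object@alpha))
    msg <- c(msg, "alpha must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: graphical feature vectors with class labels
#'
#' Holds the 34 graphical features per epoch (rows) with their class
#' labels; the canonical feature order is given by
#' [graphicalFeatureNames()].
#'
#' @slot values numeric matrix, epochs x features.
#' @slot labels class label per row.
#' @slot featureNames feature column names (F1..F34 order).
#' @seealso [extractFeatures()], [featureMatrix()], [writeFeatureMatrix()]
#' @exportClass FeatureSet
setClass("FeatureSet",
  representation(
    values = "matrix",
    labels = "character",
    featureNames = "character"
  )
)

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@values))
    msg <- c(msg, "one label per row required")
  if (length(object@featureNames) != ncol(object@values))
    msg <- c(msg, "one name per feature column required")
  if (anyNA(object@values)) msg <- c(msg, "feature values contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureSet
#'
#' @param values numeric matrix, epochs x features.
#' @param labels class label per row.
#' @param featureNames column names; defaults to the 34 canonical names
#'   when the matrix has 34 columns.
#' @return A [FeatureSet-class] object.
#' @export
FeatureSet <- function(values, labels, featureNames = NULL) {
  if (is.null(featureNames)) {
    featureNames <- if (ncol(values) == 34L) graphicalFeatureNames()
                    else sprintf("F%d", seq_len(ncol(values)))
  }
  colnames(values) <- featureNames
  new("FeatureSet", values = values, labels = as.character(labels),
      featureNames = featureNames)
}

#' SelectionResult: ensemble feature-selection scores and the chosen subset
#'
#' @slot perScorer numeric matrix, scorers x features, raw scores from the
#'   five scorers (rows \code{ig}, \code{relieff}, \code{variance},
#'   \code{nca}, \code{cfs}).
#' @slot ensemble combined (normalized, weighted) score per feature, in
#'   \code{[0, 1]}.
#' @slot selected integer indices of the K selected features, ordered by
#'   descending ensemble score (ties by lower index).
#' @slot weights the scorer weights used, normalized to sum to one.
#' @slot featureNames feature names, parallel to the score columns.
#' @seealso [ensembleSelect()], [selectedFeatures()]
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    perScorer = "matrix",
    ensemble = "numeric",
    selected = "integer",
    weights = "numeric",
    featureNames = "character"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  n <- ncol(object@perScorer)
  if (length(object@ensemble) != n)
    msg <- c(msg, "ensemble length != feature count")
  if (anyDuplicated(object@selected))
    msg <- c(msg, "selected indices must be unique")
  if (length(object@selected) &&
      (min(object@selected) < 1L || max(object@selected) > n))
    msg <- c(msg, "selected indices out of range")
  if (any(object@ensemble < -1e-12) || any(object@ensemble > 1 + 1e-12))
    msg <- c(msg, "ensemble scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' NeuralModel: a trained compact neural-network classifier
#'
#' Opaque parameter container returned by [trainClassifier()]. The
#' \code{kind} slot names one of the six supported architectures; the
#' weight list layout depends on the kind. Standardization statistics
#' estimated on the training data travel with the model so that
#' prediction applies the identical transform.
#'
#' @slot kind one of \code{"slnn"}, \code{"mlnn"}, \code{"ffnn"},
#'   \code{"cfnn"}, \code{"rnn"}, \code{"grnn"}.
#' @slot weights named list of parameter matrices/vectors (iterative
#'   kinds) or the stored training set (grnn).
#' @slot inputDim expected number of input features.
#' @slot config the [classifierConfig()] list used at training time.
#' @slot standardize list with \code{center} and \code{scale} vectors.
#' @slot trainHistory per-epoch training loss (empty for grnn).
#' @exportClass NeuralModel
setClass("NeuralModel",
  representation(
    kind = "character",
    weights = "list",
    inputDim = "integer",
    config = "list",
    standardize = "list",
    trainHistory = "numeric"
  )
)

#' CVReport: stratified cross-validation results
#'
#' @slot folds list of per-fold confusion counts (named vectors with
#'   \code{TP}, \code{FN}, \code{TN}, \code{FP}; positive class =
#'   alcoholic).
#' @slot meanMetrics mean of the per-fold metrics; sensitivity,
#'   specificity, precision, accuracy and F1 are percentages, kappa stays
#'   on its natural [-1, 1] scale.
#' @slot foldSizes integer vector \code{c(train, test)} of the first fold.
#' @slot perFoldMetrics matrix, folds x metrics.
#' @seealso [runCV()], [computeMetrics()]
#' @exportClass CVReport
setClass("CVReport",
  representation(
    folds = "list",
    meanMetrics = "numeric",
    foldSizes = "integer",
    perFoldMetrics = "matrix"
  )
)
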