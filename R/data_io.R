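#' @include AllClasses.R
NULL

#' Read a UCI-style plaintext EEG trial file
#'
#' Parses the plaintext trial format used by the UCI EEG database
#' deposit: lines starting with \code{#} are comments; every other line is
#' a whitespace-delimited row \code{trial channel-label sample-index
#' value}, with voltages in microvolts and 0-based sample indices.
#'
#' @param path path to the trial file.
#' @param fs sampling rate in Hz (the deposit used 256 Hz).
#' @param subjectClass class of the subject, if known.
#' @return An [EEGRecording-class] with one row per distinct channel
#'   label, samples ordered by sample index.
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "0 FP1 0 1.5", "0 FP1 1 2.5",
#'              "0 FP2 0 -1.0", "0 FP2 1 0.0"), f)
#' rec <- readUciTrial(f)
#' signalMatrix(rec)
#' @export
readUciTrial <- function(path, fs = 256,
                         subjectClass = c("unknown", "normal", "alcoholic")) {
  subjectClass <- match.arg(subjectClass)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data rows in ", path)
  rows <- which(keep)
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed row at line ", rows[bad[1]], ": expected 4 fields, got ",
         lengths(parts)[bad[1]])
  mat <- do.call(rbind, parts)
  chan <- mat[, 2L]
  idx <- suppressWarnings(as.integer(mat[, 3L]))
  val <- suppressWarnings(as.numeric(mat[, 4L]))
  if (anyNA(idx) || anyNA(val)) {
    bad <- which(is.na(idx) | is.na(val))[1]
    stop("malformed row at line ", rows[bad],
         ": non-numeric sample index or value")
  }
  if (anyDuplicated(paste(chan, idx)))
    stop("duplicate (channel, sample index) pair in ", path)
  labels <- unique(chan)
  per <- split(seq_along(chan), factor(chan, levels = labels))
  nsamp <- unique(lengths(per))
  if (length(nsamp) != 1L)
    stop("channels have unequal sample counts")
  samples <- matrix(0, nrow = length(labels), ncol = nsamp)
  for (i in seq_along(labels)) {
    sel <- per[[i]]
    ord <- order(idx[sel])
    samples[i, ] <- val[sel][ord]
  }
  EEGRecording(samples, channelLabels = labels, fs = fs,
               subjectClass = subjectClass)
}

#' Write a recording in the UCI-style plaintext trial format
#'
#' @param recording an [EEGRecording-class].
#' @param path output file path.
#' @param trial trial index written in the first column.
#' @return \code{path}, invisibly.
#' @seealso [readUciTrial()]
#' @export
writeUciTrial <- function(recording, path, trial = 0L) {
  stopifnot(is(recording, "EEGRecording"))
  m <- recording@samples
  hdr <- c(sprintf("# frfteeg export, %d channels, %d samples, %g Hz",
                   nrow(m), ncol(m), recording@fs),
           sprintf("# subject class: %s", recording@subjectClass))
  body <- unlist(lapply(seq_len(nrow(m)), function(i) {
    sprintf("%d %s %d %.12g", trial, recording@channelLabels[i],
            seq_len(ncol(m)) - 1L, m[i, ])
  }))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Segment a recording into fixed-length epochs
#'
#' Splits every channel into consecutive non-overlapping windows of
#' \code{epochLen} samples (half-open windows \eqn{[iL, (i+1)L)} in
#' 0-based sample coordinates). A trailing remainder shorter than
#' \code{epochLen} is dropped. Epochs inherit the recording's subject
#' class; a recording of unknown class cannot be segmented into labelled
#' epochs unless \code{label} is supplied.
#'
#' @param recording an [EEGRecording-class].
#' @param epochLen epoch length in samples (default 2048 = 8 s at 256 Hz).
#' @param label optional class label overriding the recording's class.
#' @return An [EpochSet-class]; zero epochs when the recording is shorter
#'   than \code{epochLen}.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(8192), nrow = 1), subjectClass = "normal")
#' length(segmentEpochs(rec, 2048))   # 4
#' @export
segmentEpochs <- function(recording, epochLen = 2048L, label = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  epochLen <- as.integer(epochLen)
  if (epochLen < 1L) stop("epochLen must be >= 1")
  if (is.null(label)) label <- recording@subjectClass
  if (!label %in% .CLASS_LEVELS)
    stop("recording class is '", label,
         "'; supply label = 'normal' or 'alcoholic'")
  m <- recording@samples
  nwin <- ncol(m) %/% epochLen
  if (nwin == 0L)
    return(new("EpochSet",
               samples = matrix(numeric(), 0L, epochLen),
               channel = character(), label = character(),
               artifactFlag = logical()))
  rows <- vector("list", nrow(m) * nwin)
  chan <- character(length(rows))
  p <- 0L
  for (i in seq_len(nrow(m))) {
    for (w in seq_len(nwin)) {
      p <- p + 1L
      rows[[p]] <- m[i, ((w - 1L) * epochLen + 1L):(w * epochLen)]
      chan[p] <- recording@channelLabels[i]
    }
  }
  new("EpochSet", samples = do.call(rbind, rows), channel = chan,
      label = rep(label, length(rows)),
      artifactFlag = rep(FALSE, length(rows)))
}

#' Flag epochs containing high-amplitude artifacts
#'
#' Marks an epoch as an artifact when any sample exceeds the amplitude
#' threshold in absolute value (the movement/blink screening rule,
#' default 73.3 microvolts). Samples are left untouched; use
#' [dropArtifacts()] for the filtered view.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold amplitude threshold in microvolts (> 0).
#' @return The same \code{EpochSet} with updated \code{artifactFlag}s.
#' @export
flagArtifacts <- function(epochs, threshold = 73.3) {
  stopifnot(is(epochs, "EpochSet"))
  if (threshold <= 0) stop("threshold must be positive")
  peak <- apply(abs(epochs@samples), 1L, max)
  if (nrow(epochs@samples) == 0L) peak <- numeric()
  initialize(epochs, artifactFlag = as.vector(peak > threshold))
}

#' Exclude flagged artifact epochs
#'
#' @param epochs an [EpochSet-class] (typically after [flagArtifacts()]).
#' @return The subset of epochs whose artifact flag is \code{FALSE}.
#' @export
dropArtifacts <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  epochs[!epochs@artifactFlag]
}

#' Write / read a feature matrix as CSV
#'
#' The on-disk schema is a header row \code{F1,...,F34,label} followed by
#' one row per epoch; values round-trip to 12 significant digits and
#' labels exactly.
#'
#' @param features a [FeatureSet-class] with 34 feature columns.
#' @param path CSV file path.
#' @return \code{writeFeatureMatrix}: \code{path} invisibly;
#'   \code{readFeatureMatrix}: a [FeatureSet-class].
#' @export
writeFeatureMatrix <- function(features, path) {
  stopifnot(is(features, "FeatureSet"))
  if (ncol(features@values) != 34L)
    stop("feature matrix must have exactly 34 columns")
  df <- as.data.frame(signif(features@values, 12))
  names(df) <- sprintf("F%d", 1:34)
  df$label <- features@labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  expect <- c(sprintf("F%d", 1:34), "label")
  if (length(names(df)) != length(expect) || !all(names(df) == expect)) {
    extra <- setdiff(names(df), expect)
    missing <- setdiff(expect, names(df))
    stop("feature CSV header mismatch",
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(df[, 1:34])
  if (anyNA(vals)) stop("non-numeric feature values in ", path)
  FeatureSet(vals, labels = as.character(df$label))
}
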