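#' @include AllClasses.R
NULL

.binaryLabels <- function(y) {
  lv <- unique(y)
  if (length(lv) != 2L) stop("exactly two classes required, got ",
                             length(lv))
  ## positive class = alcoholic for class-name labels, else the larger
  ## of the two sorted unique values (deterministic either way)
  pos <- if (setequal(lv, .CLASS_LEVELS)) .CLASS_LEVELS[2L]
         else sort(lv)[2L]
  as.integer(y == pos)
}

.entropyBits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Per-feature relevance scorers
#'
#' Five univariate relevance scores used by [ensembleSelect()]:
#' \describe{
#'   \item{\code{scoreInformationGain}}{mutual information (bits) between
#'     the class and the feature discretized into 10 equal-width bins:
#'     \eqn{IG = H(y) - H(y | bin(x))}. A constant feature scores 0.}
#'   \item{\code{scoreReliefF}}{ReliefF weight of one feature: all
#'     features are min-max scaled, each sample's k nearest hits and
#'     misses are found in the full feature space, and the weight is the
#'     mean absolute feature difference to misses minus to hits (larger =
#'     more relevant).}
#'   \item{\code{scoreVariance}}{population variance
#'     \eqn{\frac{1}{m}\sum (x_j - \bar x)^2} (the \code{1/m}
#'     normalization is deliberate).}
#'   \item{\code{scoreNCA}}{single-feature leave-one-out soft-neighbour
#'     score: with kernel weights
#'     \eqn{w_{jl} = \exp(-|x_j - x_l| / \hat\sigma)} and
#'     \eqn{\hat\sigma} the mean absolute pairwise difference, the score
#'     is the mean over samples of the same-class weight fraction among
#'     all other samples; lies in [0, 1].}
#'   \item{\code{scoreCFS}}{absolute Pearson correlation between the
#'     feature and the 0/1-encoded class (point-biserial); 0 for a
#'     zero-variance input.}
#' }
#'
#' @param x numeric feature column (length m).
#' @param y class labels (two classes).
#' @param X full m x n feature matrix (ReliefF only; neighbours are found
#'   in the full feature space).
#' @param featureIndex which column of \code{X} is being scored
#'   (ReliefF only).
#' @param kNeighbors neighbours per class for ReliefF (default 10;
#'   reduced to class size - 1 when a class is small).
#' @param nBins bins for the information-gain discretization (default 10).
#' @return A single numeric score.
#' @name scorers
NULL

#' @rdname scorers
#' @export
scoreInformationGain <- function(x, y, nBins = 10L) {
  y01 <- .binaryLabels(y)
  m <- length(x)
  if (m < 2L) stop("need at least 2 samples")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bins <- findInterval(x, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  hy <- .entropyBits(table(y01))
  hcond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    hcond <- hcond + mean(sel) * .entropyBits(table(y01[sel]))
  }
  max(0, hy - hcond)
}

## ReliefF weights for all features at once (distance matrix built once)
.relieffAll <- function(X, y, kNeighbors = 10L) {
  X <- as.matrix(X)
  y01 <- .binaryLabels(y)
  m <- nrow(X)
  ## min-max scale every feature so diffs are comparable
  Xs <- apply(X, 2L, function(col) {
    r <- range(col)
    if (r[1] == r[2]) rep(0, length(col)) else (col - r[1]) / (r[2] - r[1])
  })
  Xs <- matrix(Xs, nrow = m)
  D <- as.matrix(stats::dist(Xs))
  diag(D) <- Inf
  w <- numeric(ncol(Xs))
  for (j in seq_len(m)) {
    hits <- which(y01 == y01[j]); hits <- hits[hits != j]
    misses <- which(y01 != y01[j])
    kh <- min(kNeighbors, length(hits))
    km <- min(kNeighbors, length(misses))
    if (kh == 0L || km == 0L) stop("both classes need at least 2 members")
    nh <- hits[order(D[j, hits])][seq_len(kh)]
    nm <- misses[order(D[j, misses])][seq_len(km)]
    w <- w + colMeans(abs(Xs[nm, , drop = FALSE] -
                          rep(Xs[j, ], each = km))) -
             colMeans(abs(Xs[nh, , drop = FALSE] -
                          rep(Xs[j, ], each = kh)))
  }
  w / m
}

#' @rdname scorers
#' @export
scoreReliefF <- function(X, y, featureIndex, kNeighbors = 10L) {
  .relieffAll(X, y, kNeighbors = kNeighbors)[featureIndex]
}

#' @rdname scorers
#' @export
scoreVariance <- function(x) {
  m <- length(x)
  sum((x - mean(x))^2) / m
}

#' @rdname scorers
#' @export
scoreNCA <- function(x, y) {
  y01 <- .binaryLabels(y)
  m <- length(x)
  ad <- abs(outer(x, x, "-"))
  sigma <- mean(ad[upper.tri(ad)])
  if (!is.finite(sigma) || sigma == 0) sigma <- 1
  W <- exp(-ad / sigma)
  diag(W) <- 0
  same <- outer(y01, y01, "==")
  diag(same) <- FALSE
  p <- rowSums(W * same) / rowSums(W)
  mean(p)
}

#' @rdname scorers
#' @export
scoreCFS <- function(x, y) {
  y01 <- .binaryLabels(y)
  if (sd(x) == 0 || sd(y01) == 0) return(0)
  abs(cor(x, y01))
}

#' Combine per-scorer scores into an ensemble score
#'
#' Min-max normalizes each scorer's row to [0, 1] (a constant row becomes
#' all zeros) and returns the weighted mean with weights normalized to
#' sum to one.
#'
#' @param perScorer numeric matrix, scorers x features.
#' @param weights non-negative scorer weights (default equal).
#' @return Numeric vector of ensemble scores, one per feature.
#' @examples
#' combineScores(rbind(c(2, 4, 6)), weights = 1)  # 0, 0.5, 1
#' @export
combineScores <- function(perScorer, weights = rep(1, nrow(perScorer))) {
  perScorer <- as.matrix(perScorer)
  if (length(weights) != nrow(perScorer))
    stop("one weight per scorer required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  normed <- t(apply(perScorer, 1L, function(row) {
    r <- range(row)
    if (r[1] == r[2]) rep(0, length(row)) else (row - r[1]) / (r[2] - r[1])
  }))
  w <- weights / sum(weights)
  as.numeric(crossprod(normed, w))
}

#' Select the K highest-scoring features
#'
#' Ties are broken in favour of the lower feature index; the result is
#' ordered by descending score, then index.
#'
#' @param ensemble numeric score per feature.
#' @param k number of features to keep (1..length(ensemble)).
#' @return Integer indices of the selected features.
#' @examples
#' selectTopK(c(0.9, 0.2, 0.9, 0.5), 2)  # 1, 3
#' @export
selectTopK <- function(ensemble, k) {
  n <- length(ensemble)
  if (k < 1L || k > n) stop("k must lie in 1..", n)
  order(-ensemble, seq_len(n))[seq_len(k)]
}

#' Ensemble feature selection
#'
#' Scores every feature with the five scorers (information gain, ReliefF,
#' variance, NCA, CFS; see [scorers]), combines them with
#' [combineScores()], and keeps the top \code{k}. With
#' \code{mode = "cfs"} the selection uses the CFS (point-biserial
#' correlation) score alone; the score tables are reported either way.
#'
#' @param features a [FeatureSet-class] or a numeric matrix.
#' @param labels class labels (needed when \code{features} is a matrix).
#' @param k number of features to select (default 16).
#' @param weights scorer weights (default equal).
#' @param mode \code{"ensemble"} (default) or \code{"cfs"}.
#' @param kNeighbors ReliefF neighbourhood size.
#' @return A [SelectionResult-class].
#' @examples
#' cfg <- synthConfig(nTrialsPerClass = 10, epochLen = 256, seed = 7)
#' fs <- epochFeatures(generateDataset(cfg))
#' sel <- ensembleSelect(fs, k = 5)
#' selectedFeatures(sel)
#' @export
ensembleSelect <- function(features, labels = NULL, k = 16L,
                           weights = rep(1, 5), mode = c("ensemble", "cfs"),
                           kNeighbors = 10L) {
  mode <- match.arg(mode)
  if (is(features, "FeatureSet")) {
    X <- featureMatrix(features)
    labels <- epochLabels(features)
    fnames <- features@featureNames
  } else {
    X <- as.matrix(features)
    if (is.null(labels)) stop("labels required for a plain matrix")
    fnames <- colnames(X)
    if (is.null(fnames)) fnames <- sprintf("F%d", seq_len(ncol(X)))
  }
  if (anyNA(X)) stop("feature matrix contains NA")
  n <- ncol(X)
  per <- matrix(0, 5L, n,
                dimnames = list(c("ig", "relieff", "variance", "nca",
                                  "cfs"), fnames))
  per["relieff", ] <- .relieffAll(X, labels, kNeighbors = kNeighbors)
  for (i in seq_len(n)) {
    per["ig", i] <- scoreInformationGain(X[, i], labels)
    per["variance", i] <- scoreVariance(X[, i])
    per["nca", i] <- scoreNCA(X[, i], labels)
    per["cfs", i] <- scoreCFS(X[, i], labels)
  }
  ens <- if (mode == "ensemble") combineScores(per, weights)
         else combineScores(per["cfs", , drop = FALSE], 1)
  sel <- selectTopK(ens, k)
  new("SelectionResult", perScorer = per, ensemble = ens,
      selected = as.integer(sel),
      weights = weights / sum(weights), featureNames = fnames)
}

#' Feature subset reported for the reference configuration
#'
#' The 16-feature subset used by the best-performing published
#' configuration of this workflow, as a named preset:
#' F1, F7, F8, F9, F10, F13, F14, F19, F26, F27, F29, F30, F31, F32,
#' F33, F34 (indices into the canonical feature order).
#'
#' @return Integer vector of 16 feature indices.
#' @export
referenceFeatureSubset <- function() {
  c(1L, 7L, 8L, 9L, 10L, 13L, 14L, 19L, 26L, 27L, 29L, 30L, 31L, 32L,
    33L, 34L)
}
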