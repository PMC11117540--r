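#' @include classifiers.R selection.R
NULL

#' Stratified k-fold partition
#'
#' Shuffles the sample indices with the seeded generator and deals each
#' class round-robin into \code{k} folds, so every fold's class ratio is
#' within one sample of the global ratio. Folds are disjoint and
#' exhaustive.
#'
#' @param labels class label per sample.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return List of \code{k} integer vectors (test indices per fold).
#' @examples
#' folds <- stratifiedKFold(rep(c("normal", "alcoholic"), each = 120),
#'                          k = 10, seed = 42)
#' lengths(folds)  # all 24
#' @export
stratifiedKFold <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  tab <- table(labels)
  if (any(tab < k))
    stop("k = ", k, " exceeds the size of the smallest class (",
         min(tab), ")")
  withSeed(seed, {
    folds <- vector("list", k)
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      assignment <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[assignment == f])
    }
    lapply(folds, sort)
  })
}

#' Confusion counts from predicted and true labels
#'
#' The positive class is \code{"alcoholic"}.
#'
#' @param predicted,truth label vectors of equal length.
#' @return Named integer vector with \code{TP}, \code{FN}, \code{TN},
#'   \code{FP}.
#' @export
confusionCounts <- function(predicted, truth) {
  pos <- if (any(truth == .CLASS_LEVELS[2L])) .CLASS_LEVELS[2L]
         else sort(unique(truth))[2L]
  c(TP = sum(predicted == pos & truth == pos),
    FN = sum(predicted != pos & truth == pos),
    TN = sum(predicted != pos & truth != pos),
    FP = sum(predicted == pos & truth != pos))
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, precision, accuracy, F1 (all as
#' percentages) and Cohen's kappa (on its natural [-1, 1] scale) from a
#' confusion-count vector. A metric whose denominator is zero is
#' reported as 0 with a warning.
#'
#' @param counts named vector with \code{TP}, \code{FN}, \code{TN},
#'   \code{FP} (the order does not matter).
#' @return Named numeric vector of the six metrics.
#' @examples
#' round(computeMetrics(c(TP = 116, FN = 4, TN = 118, FP = 2)), 1)
#' @export
computeMetrics <- function(counts) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion counts")
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); 0 }
    else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  acc <- (tp + tn) / total
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  c(sensitivity = 100 * sens, specificity = 100 * spec,
    precision = 100 * prec, accuracy = 100 * acc, f1 = 100 * f1,
    kappa = kappa)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value
#' on \code{groups - 1} degrees of freedom; used to screen individual
#' features for class differences. Identical values across all groups
#' give H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return Named numeric vector \code{c(H, p)}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))  # H ~ 3.857
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) == 0L)) stop("groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  tieCorr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (tieCorr == 0) 0 else H / tieCorr
  p <- if (H == 0) 1 else pchisq(H, df = length(groups) - 1L,
                                 lower.tail = FALSE)
  c(H = H, p = p)
}

#' Kruskal-Wallis screening of every feature
#'
#' @param features a [FeatureSet-class].
#' @return Data frame with one row per feature: H statistic, p-value and
#'   per-class means and standard deviations.
#' @export
screenFeatures <- function(features) {
  stopifnot(is(features, "FeatureSet"))
  X <- featureMatrix(features)
  y <- epochLabels(features)
  out <- lapply(seq_len(ncol(X)), function(i) {
    byg <- split(X[, i], y)
    kw <- kruskalWallis(byg)
    data.frame(feature = features@featureNames[i],
               H = kw[["H"]], p = kw[["p"]],
               meanNormal = mean(byg$normal),
               sdNormal = sd(byg$normal),
               meanAlcoholic = mean(byg$alcoholic),
               sdAlcoholic = sd(byg$alcoholic))
  })
  do.call(rbind, out)
}

#' Stratified cross-validated evaluation of a classifier
#'
#' For each fold, feature standardization (inside [trainClassifier()])
#' and - when \code{selection = "fold"} - feature selection are fitted on
#' the training split only; the trained model is then evaluated on the
#' held-out fold. \code{selection = "global"} performs one selection on
#' the full data before cross-validation (the optimistic variant some
#' published workflows use); \code{selection = "none"} uses all feature
#' columns.
#'
#' @param features a [FeatureSet-class] (or numeric matrix with
#'   \code{labels}).
#' @param labels labels when \code{features} is a matrix.
#' @param config a [classifierConfig()] or architecture name.
#' @param k number of folds (default 10).
#' @param seed seed controlling the fold shuffle and weight inits.
#' @param selection \code{"none"}, \code{"fold"} or \code{"global"}.
#' @param nSelect number of features kept by selection (default 16).
#' @param selectionMode passed to [ensembleSelect()] (\code{"ensemble"}
#'   or \code{"cfs"}).
#' @return A [CVReport-class].
#' @export
runCV <- function(features, labels = NULL, config = "rnn", k = 10L,
                  seed = 1L, selection = c("none", "fold", "global"),
                  nSelect = 16L, selectionMode = "ensemble") {
  selection <- match.arg(selection)
  if (is(features, "FeatureSet")) {
    X <- featureMatrix(features)
    labels <- epochLabels(features)
  } else {
    X <- as.matrix(features)
    if (is.null(labels)) stop("labels required for a plain matrix")
  }
  if (is.character(config)) config <- classifierConfig(config)
  folds <- stratifiedKFold(labels, k = k, seed = seed)
  if (selection == "global") {
    sel <- ensembleSelect(X, labels, k = nSelect, mode = selectionMode)
    X <- X[, selectedFeatures(sel), drop = FALSE]
  }
  metricNames <- c("sensitivity", "specificity", "precision", "accuracy",
                   "f1", "kappa")
  perFold <- matrix(0, k, length(metricNames),
                    dimnames = list(NULL, metricNames))
  confusions <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(labels), test)
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (selection == "fold") {
      sel <- ensembleSelect(Xtr, labels[train], k = nSelect,
                            mode = selectionMode)
      Xtr <- Xtr[, selectedFeatures(sel), drop = FALSE]
      Xte <- Xte[, selectedFeatures(sel), drop = FALSE]
    }
    model <- trainClassifier(config, Xtr, labels[train],
                             seed = config$seed + f)
    pred <- predict(model, Xte)
    confusions[[f]] <- confusionCounts(pred, labels[test])
    perFold[f, ] <- suppressWarnings(computeMetrics(confusions[[f]]))
  }
  new("CVReport", folds = confusions,
      meanMetrics = colMeans(perFold),
      foldSizes = c(length(labels) - length(folds[[1]]),
                    length(folds[[1]])),
      perFoldMetrics = perFold)
}
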