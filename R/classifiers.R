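#' @include AllClasses.R synthetic.R
NULL

.CLASSIFIER_KINDS <- c("slnn", "mlnn", "ffnn", "cfnn", "rnn", "grnn")

#' Classifier configuration with per-architecture defaults
#'
#' Builds the hyperparameter list for [trainClassifier()]. The defaults
#' per architecture are: single-layer network (slnn) 50 ReLU units,
#' learning rate 0.01, 100 epochs; multilayer network (mlnn) two tanh
#' layers of 100 units, rate 0.05, 200 epochs; feed-forward network
#' (ffnn) 200 sigmoid units, rate 0.1, 150 epochs; cascade-forward
#' network (cfnn) 100 ReLU units plus direct input-to-output connections,
#' rate 0.01, 100 epochs; Elman recurrent network (rnn) 50 tanh units,
#' rate 0.01, 200 epochs; generalized regression network (grnn) Gaussian
#' kernel with sigma 0.5 and confidence radius 0.1 (no iterative
#' training).
#'
#' @param kind one of \code{"slnn"}, \code{"mlnn"}, \code{"ffnn"},
#'   \code{"cfnn"}, \code{"rnn"}, \code{"grnn"}.
#' @param learningRate,hiddenUnits,activation,epochs overrides of the
#'   per-kind defaults.
#' @param sigma Gaussian kernel width (grnn only).
#' @param radius kernel-mass floor below which the grnn falls back to the
#'   training majority class (grnn only).
#' @param seed seed for the weight initialization.
#' @return Named list of class \code{"classifierConfig"}.
#' @examples
#' classifierConfig("rnn")
#' @export
classifierConfig <- function(kind = .CLASSIFIER_KINDS,
                             learningRate = NULL, hiddenUnits = NULL,
                             activation = NULL, epochs = NULL,
                             sigma = 0.5, radius = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    slnn = list(learningRate = 0.01, hiddenUnits = 50L,
                activation = "relu", epochs = 100L),
    mlnn = list(learningRate = 0.05, hiddenUnits = 100L,
                activation = "tanh", epochs = 200L),
    ffnn = list(learningRate = 0.1, hiddenUnits = 200L,
                activation = "sigmoid", epochs = 150L),
    cfnn = list(learningRate = 0.01, hiddenUnits = 100L,
                activation = "relu", epochs = 100L),
    rnn  = list(learningRate = 0.01, hiddenUnits = 50L,
                activation = "tanh", epochs = 200L),
    grnn = list(learningRate = NA_real_, hiddenUnits = NA_integer_,
                activation = "gaussian", epochs = NA_integer_)
  )
  cfg <- list(
    kind = kind,
    learningRate = if (is.null(learningRate)) defaults$learningRate
                   else learningRate,
    hiddenUnits = if (is.null(hiddenUnits)) defaults$hiddenUnits
                  else as.integer(hiddenUnits),
    activation = if (is.null(activation)) defaults$activation
                 else match.arg(activation,
                                c("relu", "tanh", "sigmoid", "gaussian")),
    epochs = if (is.null(epochs)) defaults$epochs else as.integer(epochs),
    sigma = sigma, radius = radius, seed = as.integer(seed)
  )
  if (kind != "grnn") {
    if (cfg$learningRate <= 0) stop("learningRate must be positive")
    if (cfg$epochs < 1L) stop("epochs must be >= 1")
  }
  structure(cfg, class = "classifierConfig")
}

.actFun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a)),
    stop("unsupported activation: ", name))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.xentropy <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

.initMat <- function(nr, nc) matrix(runif(nr * nc, -0.5, 0.5), nr, nc)

## ---- feed-forward family (slnn, mlnn, ffnn, cfnn) ----

.mlpInit <- function(kind, inputDim, hidden, cfg) {
  sizes <- switch(kind,
    slnn = hidden, ffnn = hidden, cfnn = hidden,
    mlnn = c(hidden, hidden))
  dims <- c(inputDim, sizes)
  W <- lapply(seq_along(sizes), function(l) .initMat(dims[l + 1], dims[l]))
  b <- lapply(sizes, function(s) runif(s, -0.5, 0.5))
  wOut <- runif(sizes[length(sizes)], -0.5, 0.5)
  bOut <- runif(1, -0.5, 0.5)
  params <- list(W = W, b = b, wOut = wOut, bOut = bOut)
  if (kind == "cfnn") params$wSkip <- runif(inputDim, -0.5, 0.5)
  params
}

.mlpForward <- function(params, X, act) {
  A <- list(); Z <- list()
  cur <- X                           # m x d
  for (l in seq_along(params$W)) {
    z <- cur %*% t(params$W[[l]])
    z <- sweep(z, 2L, params$b[[l]], "+")
    a <- act$f(z)
    Z[[l]] <- z; A[[l]] <- a
    cur <- a
  }
  zo <- drop(cur %*% params$wOut) + params$bOut
  if (!is.null(params$wSkip)) zo <- zo + drop(X %*% params$wSkip)
  list(A = A, Z = Z, p = .sigmoid(zo))
}

.mlpTrain <- function(kind, X, y, cfg) {
  act <- .actFun(cfg$activation)
  params <- .mlpInit(kind, ncol(X), cfg$hiddenUnits, cfg)
  m <- nrow(X)
  history <- numeric(cfg$epochs)
  lr <- cfg$learningRate
  for (ep in seq_len(cfg$epochs)) {
    fw <- .mlpForward(params, X, act)
    history[ep] <- .xentropy(fw$p, y)
    delta <- (fw$p - y) / m          # m-vector, dL/dz_out
    L <- length(params$W)
    gWout <- drop(crossprod(fw$A[[L]], delta))
    gBout <- sum(delta)
    if (!is.null(params$wSkip)) gSkip <- drop(crossprod(X, delta))
    dA <- outer(delta, params$wOut)  # m x units(L)
    gW <- vector("list", L); gB <- vector("list", L)
    for (l in rev(seq_len(L))) {
      dZ <- dA * act$df(fw$Z[[l]], fw$A[[l]])
      below <- if (l == 1L) X else fw$A[[l - 1L]]
      gW[[l]] <- crossprod(dZ, below)   # units(l) x units(l-1)
      gB[[l]] <- colSums(dZ)
      if (l > 1L) dA <- dZ %*% params$W[[l]]
    }
    for (l in seq_len(L)) {
      params$W[[l]] <- params$W[[l]] - lr * gW[[l]]
      params$b[[l]] <- params$b[[l]] - lr * gB[[l]]
    }
    params$wOut <- params$wOut - lr * gWout
    params$bOut <- params$bOut - lr * gBout
    if (!is.null(params$wSkip)) params$wSkip <- params$wSkip - lr * gSkip
  }
  list(params = params, history = history)
}

.mlpPredict <- function(params, X, activation) {
  .mlpForward(params, X, .actFun(activation))$p
}

## ---- Elman RNN over the feature vector as a sequence ----

.rnnTrain <- function(X, y, cfg) {
  H <- cfg$hiddenUnits
  d <- ncol(X); m <- nrow(X)
  params <- list(wx = runif(H, -0.5, 0.5), Wh = .initMat(H, H),
                 bh = runif(H, -0.5, 0.5), wOut = runif(H, -0.5, 0.5),
                 bOut = runif(1, -0.5, 0.5))
  lr <- cfg$learningRate
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ## forward: h_t = tanh(wx * x_t + Wh h_{t-1} + bh), one feature/step
    Hs <- vector("list", d)
    h <- matrix(0, m, H)
    for (t in seq_len(d)) {
      z <- outer(X[, t], params$wx) + h %*% t(params$Wh)
      z <- sweep(z, 2L, params$bh, "+")
      h <- tanh(z)
      Hs[[t]] <- h
    }
    p <- .sigmoid(drop(h %*% params$wOut) + params$bOut)
    history[ep] <- .xentropy(p, y)
    delta <- (p - y) / m
    gWout <- drop(crossprod(h, delta))
    gBout <- sum(delta)
    dH <- outer(delta, params$wOut)
    gwx <- numeric(H); gWh <- matrix(0, H, H); gbh <- numeric(H)
    for (t in rev(seq_len(d))) {
      a <- Hs[[t]]
      dZ <- dH * (1 - a^2)
      gwx <- gwx + drop(crossprod(dZ, X[, t]))
      prev <- if (t > 1L) Hs[[t - 1L]] else matrix(0, m, H)
      gWh <- gWh + crossprod(dZ, prev)
      gbh <- gbh + colSums(dZ)
      dH <- dZ %*% params$Wh
    }
    params$wx <- params$wx - lr * gwx
    params$Wh <- params$Wh - lr * gWh
    params$bh <- params$bh - lr * gbh
    params$wOut <- params$wOut - lr * gWout
    params$bOut <- params$bOut - lr * gBout
  }
  list(params = params, history = history)
}

.rnnPredict <- function(params, X) {
  m <- nrow(X); H <- length(params$wx)
  h <- matrix(0, m, H)
  for (t in seq_len(ncol(X))) {
    z <- outer(X[, t], params$wx) + h %*% t(params$Wh)
    h <- tanh(sweep(z, 2L, params$bh, "+"))
  }
  .sigmoid(drop(h %*% params$wOut) + params$bOut)
}

## ---- GRNN ----

.grnnPredict <- function(params, X) {
  sig2 <- 2 * params$sigma^2
  vapply(seq_len(nrow(X)), function(i) {
    d2 <- rowSums(sweep(params$X, 2L, X[i, ], "-")^2)
    w <- exp(-d2 / sig2)
    tot <- sum(w)
    if (tot < params$radius * nrow(params$X) * .Machine$double.eps)
      return(params$majority)
    sum(w * params$y) / tot
  }, numeric(1))
}

#' Train a neural-network classifier on feature vectors
#'
#' Features are z-score standardized with statistics estimated from the
#' training data (stored in the model and re-applied at prediction
#' time). Iterative architectures are trained with full-batch gradient
#' descent on the cross-entropy loss, weights initialized uniformly in
#' [-0.5, 0.5] from the seeded generator; the grnn simply stores the
#' standardized training set. The positive class (output 1) is
#' \code{"alcoholic"} when labels are class names, otherwise the larger
#' of the two sorted unique labels.
#'
#' @param config a [classifierConfig()] (or an architecture name, which
#'   is expanded with default parameters).
#' @param X numeric matrix, samples x features.
#' @param y labels with exactly two classes.
#' @param seed overrides the config seed when given.
#' @return A [NeuralModel-class].
#' @examples
#' X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
#' y <- rep(c("normal", "alcoholic"), each = 30)
#' fit <- trainClassifier("slnn", X, y)
#' mean(predict(fit, X) == y)
#' @export
trainClassifier <- function(config, X, y, seed = NULL) {
  if (is.character(config)) config <- classifierConfig(config)
  stopifnot(inherits(config, "classifierConfig"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  y01 <- .binaryLabels(y)
  if (length(unique(y01)) != 2L) stop("both classes must be present")
  lv <- unique(as.character(y))
  config$labels <- c(lv[y01[match(lv, y)] == 0L][1L],
                     lv[y01[match(lv, y)] == 1L][1L])
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  fit <- withSeed(config$seed, {
    switch(config$kind,
      grnn = list(params = list(X = Xs, y = y01, sigma = config$sigma,
                                radius = config$radius,
                                majority = as.numeric(
                                  mean(y01) >= 0.5)),
                  history = numeric()),
      rnn = .rnnTrain(Xs, y01, config),
      .mlpTrain(config$kind, Xs, y01, config))
  })
  new("NeuralModel", kind = config$kind, weights = fit$params,
      inputDim = ncol(X), config = unclass(config),
      standardize = list(center = center, scale = scale),
      trainHistory = fit$history)
}

#' Predict class labels or scores from a trained model
#'
#' @param object a [NeuralModel-class].
#' @param newdata numeric matrix, samples x features (same feature count
#'   as at training time).
#' @param type \code{"class"} (default) for labels at the 0.5 threshold,
#'   \code{"score"} for the raw probability-like output in [0, 1].
#' @return Character labels (\code{"normal"}/\code{"alcoholic"}) or
#'   numeric scores.
#' @export
setMethod("predict", "NeuralModel", function(object, newdata,
                                             type = c("class", "score")) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object@inputDim)
    stop("expected ", object@inputDim, " features, got ", ncol(X))
  Xs <- sweep(sweep(X, 2L, object@standardize$center), 2L,
              object@standardize$scale, "/")
  score <- switch(object@kind,
    grnn = .grnnPredict(object@weights, Xs),
    rnn = .rnnPredict(object@weights, Xs),
    .mlpPredict(object@weights, Xs, object@config$activation))
  if (type == "score") return(score)
  lv <- object@config$labels
  if (is.null(lv)) lv <- .CLASS_LEVELS
  ifelse(score >= 0.5, lv[2L], lv[1L])
})
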