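makeBlobs <- function(n, gap, seed) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, mean = gap), n))
  list(X = X, y = rep(c("normal", "alcoholic"), each = n))
}

test_that("per-architecture defaults are as configured", {
  expect_equal(classifierConfig("slnn")[c("learningRate", "hiddenUnits",
                                          "activation", "epochs")],
               list(learningRate = 0.01, hiddenUnits = 50L,
                    activation = "relu", epochs = 100L))
  expect_equal(classifierConfig("mlnn")$learningRate, 0.05)
  expect_equal(classifierConfig("ffnn")$hiddenUnits, 200L)
  expect_equal(classifierConfig("cfnn")$activation, "relu")
  expect_equal(classifierConfig("rnn")$epochs, 200L)
  g <- classifierConfig("grnn")
  expect_equal(g$sigma, 0.5)
  expect_equal(g$radius, 0.1)
  expect_error(classifierConfig("slnn", learningRate = -1), "positive")
})

test_that("a single-layer network separates well-separated blobs", {
  d <- makeBlobs(100, gap = 4, seed = 50)
  fit <- trainClassifier("slnn", d$X, d$y, seed = 1)
  expect_equal(mean(predict(fit, d$X) == d$y), 1.0)
  # held-out generalization on a fresh draw
  d2 <- makeBlobs(100, gap = 4, seed = 51)
  expect_gt(mean(predict(fit, d2$X) == d2$y), 0.95)
  # training loss decreased
  h <- fit@trainHistory
  expect_lt(h[length(h)], h[1])
})

test_that("a two-layer tanh network solves XOR", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("normal", "alcoholic", "alcoholic", "normal")
  fit <- trainClassifier(classifierConfig("mlnn", epochs = 2000), X, y,
                         seed = 1)
  expect_equal(mean(predict(fit, X) == y), 1.0)
})

test_that("training is deterministic under a fixed seed", {
  d <- makeBlobs(30, gap = 3, seed = 52)
  for (kind in c("slnn", "mlnn", "ffnn", "cfnn", "rnn")) {
    f1 <- trainClassifier(kind, d$X, d$y, seed = 9)
    f2 <- trainClassifier(kind, d$X, d$y, seed = 9)
    expect_identical(f1@weights, f2@weights)
    expect_identical(predict(f1, d$X, type = "score"),
                     predict(f2, d$X, type = "score"))
  }
})

test_that("all six architectures learn an easy separable task", {
  d <- makeBlobs(50, gap = 4, seed = 53)
  d2 <- makeBlobs(50, gap = 4, seed = 54)
  for (kind in c("slnn", "mlnn", "ffnn", "cfnn", "rnn", "grnn")) {
    fit <- trainClassifier(kind, d$X, d$y, seed = 2)
    expect_gt(mean(predict(fit, d2$X) == d2$y), 0.9)
  }
})

test_that("the GRNN kernel average behaves at its limits", {
  X <- rbind(c(0, 0), c(2, 2))
  y <- c("normal", "alcoholic")
  g <- trainClassifier(classifierConfig("grnn", sigma = 0.01), X, y)
  expect_equal(predict(g, X), y)
  # midpoint of two symmetric opposite-label points scores exactly 0.5
  gm <- trainClassifier(classifierConfig("grnn", sigma = 1), X, y)
  expect_equal(predict(gm, rbind(c(1, 1)), type = "score"), 0.5)
  # grnn prediction does not depend on training-set order
  ord <- c(2, 1)
  g2 <- trainClassifier(classifierConfig("grnn", sigma = 1),
                        X[ord, ], y[ord])
  q <- rbind(c(0.3, 1.2), c(1.5, 0.1))
  expect_equal(predict(gm, q, type = "score"),
               predict(g2, q, type = "score"))
})

test_that("invalid training and prediction inputs are rejected", {
  X <- matrix(rnorm(20), 10)
  expect_error(trainClassifier("slnn", X, rep("normal", 10)),
               "two classes")
  Xna <- X; Xna[1] <- NA
  expect_error(trainClassifier("slnn", Xna,
                               rep(c("normal", "alcoholic"), 5)), "finite")
  fit <- trainClassifier("slnn", X, rep(c("normal", "alcoholic"), 5))
  expect_error(predict(fit, matrix(rnorm(9), 3)), "expected 2 features")
})
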