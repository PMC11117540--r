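test_that("information gain matches hand-computed binning cases", {
  expect_equal(scoreInformationGain(c(1, 1, 2, 2), c(0, 0, 1, 1)), 1.0)
  expect_equal(scoreInformationGain(rep(5, 10), rep(0:1, 5)), 0)
  expect_equal(scoreInformationGain(c(1.0, 1.1, 9.0, 9.1), c(0, 0, 1, 1)),
               1.0)
})

test_that("variance scorer uses the 1/m normalization", {
  expect_equal(scoreVariance(c(0, 2)), 1.0)
  expect_equal(scoreVariance(rep(3, 7)), 0)
  expect_equal(scoreVariance(c(1, 2, 3)), 2 / 3)
})

test_that("NCA soft-neighbour score hits its closed-form limits", {
  y <- rep(0:1, each = 50)
  expect_equal(scoreNCA(rep(1, 100), y), 49 / 99)
  # widely separated balanced clusters: sigma-hat tracks the separation
  # (mean |pairwise diff| -> 0.50505 d), so the score saturates at
  # 49 / (49 + 50 exp(-1/0.50505)) ~ 0.8765 rather than approaching 1
  set.seed(40)
  x <- c(rnorm(50, 0, 0.01), rnorm(50, 100, 0.01))
  expect_equal(scoreNCA(x, y), 49 / (49 + 50 * exp(-1 / (2500 / 4950))),
               tolerance = 1e-3)
  # permutation null: score stays near the class-prior mix
  devs <- vapply(1:20, function(s) {
    set.seed(s)
    scoreNCA(rnorm(100), sample(y))
  }, numeric(1))
  expect_true(all(abs(devs - 49 / 99) < 0.05))
})

test_that("CFS reduces to the absolute point-biserial correlation", {
  expect_equal(scoreCFS(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(scoreCFS(rep(2, 6), rep(0:1, 3)), 0)
  expect_equal(scoreCFS(c(1, 2, 3, 4), c(0, 0, 1, 1)), 0.89443,
               tolerance = 1e-4)
})

test_that("ReliefF ranks a label-copy feature first and nulls to ~0", {
  set.seed(41)
  y <- rep(c("normal", "alcoholic"), each = 100)
  X <- matrix(rnorm(200 * 10), 200)
  X[, 4] <- as.numeric(y == "alcoholic")
  scores <- vapply(1:10, function(i) scoreReliefF(X, y, i), numeric(1))
  expect_equal(which.max(scores), 4L)

  expect_equal(scoreReliefF(cbind(rep(1, 200), X[, 1]), y, 1), 0)

  set.seed(42)
  Xn <- matrix(runif(500 * 3), 500)
  expect_lt(abs(scoreReliefF(Xn, rep(c("normal", "alcoholic"), 250), 1)),
            0.1)
})

test_that("score combination normalizes rows and honours the weights", {
  expect_equal(combineScores(rbind(c(2, 4, 6)), weights = 1),
               c(0, 0.5, 1))
  per <- rbind(c(2, 4, 6), c(2, 4, 6), c(2, 4, 6), c(2, 4, 6), c(2, 4, 6))
  expect_equal(combineScores(per), c(0, 0.5, 1))
  per2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  expect_equal(combineScores(per2, weights = c(1, 0, 0, 0, 0)),
               c(1, 0, 0))
  expect_equal(combineScores(rbind(rep(7, 4), c(0, 1, 2, 3)))[1], 0)
  expect_error(combineScores(per, weights = rep(0, 5)), "zero")
})

test_that("top-K selection breaks ties towards the lower index", {
  expect_equal(selectTopK(c(0.9, 0.2, 0.9, 0.5), 2), c(1L, 3L))
  expect_equal(selectTopK(c(0.3, 0.2, 0.1), 3), 1:3)
  expect_equal(selectTopK(c(5, 4, 3), 1), 1L)
  expect_error(selectTopK(c(1, 2), 3), "1..2")
})

test_that("the ensemble recovers planted informative features", {
  hits <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(240 * 34), 240)
    y <- rep(c("normal", "alcoholic"), each = 120)
    X[y == "alcoholic", 1:5] <- X[y == "alcoholic", 1:5] + 1.5
    length(intersect(selectedFeatures(ensembleSelect(X, y, k = 5)), 1:5))
  }, numeric(1))
  expect_true(all(hits >= 4))
})

test_that("IG, CFS and NCA are invariant to affine feature rescaling", {
  set.seed(43)
  x <- rnorm(80)
  y <- rep(c("normal", "alcoholic"), 40)
  for (f in list(function(v) 3 * v + 7, function(v) -0.2 * v + 1)) {
    expect_equal(scoreInformationGain(f(x), y),
                 scoreInformationGain(x, y), tolerance = 1e-12)
    expect_equal(scoreCFS(f(x), y), scoreCFS(x, y), tolerance = 1e-12)
    expect_equal(scoreNCA(f(x), y), scoreNCA(x, y), tolerance = 1e-9)
  }
})

test_that("selection result exposes scores, modes and the reference preset", {
  set.seed(44)
  X <- matrix(rnorm(60 * 6), 60)
  y <- rep(c("normal", "alcoholic"), each = 30)
  sel <- ensembleSelect(X, y, k = 3)
  expect_equal(dim(scorerScores(sel)), c(5L, 6L))
  expect_length(selectedFeatures(sel), 3L)
  expect_true(all(ensembleScores(sel) >= 0 & ensembleScores(sel) <= 1))

  cfs <- ensembleSelect(X, y, k = 3, mode = "cfs")
  expect_equal(selectedFeatures(cfs),
               selectTopK(scorerScores(cfs)["cfs", ], 6)[1:3])

  expect_length(referenceFeatureSubset(), 16L)
  expect_true(all(referenceFeatureSubset() %in% 1:34))
})
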