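test_that("stratified folds partition the data with balanced classes", {
  y <- rep(c("normal", "alcoholic"), each = 120)
  folds <- stratifiedKFold(y, k = 10, seed = 42)
  expect_length(folds, 10L)
  expect_true(all(lengths(folds) == 24L))
  expect_equal(sort(unlist(folds)), 1:240)
  for (f in folds)
    expect_equal(as.vector(table(y[f])), c(12L, 12L))

  expect_identical(stratifiedKFold(y, 10, seed = 7),
                   stratifiedKFold(y, 10, seed = 7))

  small <- stratifiedKFold(rep(c("normal", "alcoholic"), 10), k = 10,
                           seed = 1)
  expect_true(all(lengths(small) == 2L))
  expect_error(stratifiedKFold(rep(c("normal", "alcoholic"), 3), k = 10),
               "smallest class")
})

test_that("metrics arithmetic reproduces hand-checked confusions", {
  m <- computeMetrics(c(TP = 116, FN = 4, TN = 118, FP = 2))
  expect_equal(round(m[["accuracy"]], 1), 97.5)
  expect_equal(round(m[["sensitivity"]], 1), 96.7)
  expect_equal(round(m[["specificity"]], 1), 98.3)

  perfect <- computeMetrics(c(TP = 10, FN = 0, TN = 10, FP = 0))
  expect_equal(unname(perfect[c("sensitivity", "specificity", "precision",
                                "accuracy", "f1")]), rep(100, 5))
  expect_equal(perfect[["kappa"]], 1.0)

  allPos <- suppressWarnings(
    computeMetrics(c(TP = 50, FN = 0, TN = 0, FP = 50)))
  expect_equal(allPos[["kappa"]], 0.0)
  warns <- capture_warnings(computeMetrics(c(TP = 0, FN = 0, TN = 5,
                                             FP = 0)))
  expect_match(warns, "sensitivity", all = FALSE)
  expect_match(warns, "precision", all = FALSE)
})

test_that("confusion counts treat alcoholic as the positive class", {
  truth <- c("alcoholic", "alcoholic", "normal", "normal")
  pred <- c("alcoholic", "normal", "normal", "alcoholic")
  expect_equal(confusionCounts(pred, truth),
               c(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
})

test_that("Kruskal-Wallis statistic matches hand-computed rank sums", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  # ranks 1..6, group mean ranks 2 and 5, overall (n+1)/2 = 3.5
  expect_equal(kw[["H"]], 12 / (6 * 7) * (3 * 1.5^2 + 3 * 1.5^2),
               tolerance = 1e-10)
  expect_equal(kw[["H"]], 3.857, tolerance = 1e-3)

  same <- kruskalWallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same[["H"]], 0)
  expect_equal(same[["p"]], 1)

  # agreement with the reference implementation on a random case
  set.seed(60)
  g1 <- rnorm(20); g2 <- rnorm(20, 1)
  ours <- kruskalWallis(list(g1, g2))
  ref <- kruskal.test(list(g1, g2))
  expect_equal(ours[["H"]], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours[["p"]], ref$p.value, tolerance = 1e-10)

  # monotonicity: wider separation never shrinks H
  h1 <- kruskalWallis(list(1:4, c(3, 5, 6, 7)))[["H"]]
  h2 <- kruskalWallis(list(1:4, c(13, 15, 16, 17)))[["H"]]
  expect_gte(h2, h1)
})

test_that("feature screening reports per-class moments and p-values", {
  set.seed(61)
  X <- matrix(rnorm(40 * 34), 40)
  X[1:20, 2] <- X[1:20, 2] + 3
  fs <- FeatureSet(X, labels = rep(c("normal", "alcoholic"), each = 20))
  scr <- screenFeatures(fs)
  expect_equal(nrow(scr), 34L)
  expect_lt(scr$p[2], 0.01)
  expect_gt(scr$meanNormal[2], scr$meanAlcoholic[2])
})

test_that("cross-validation wires selection, training and metrics together", {
  set.seed(62)
  X <- rbind(matrix(rnorm(40 * 8), 40),
             matrix(rnorm(40 * 8, mean = 2), 40))
  y <- rep(c("normal", "alcoholic"), each = 40)
  rep1 <- runCV(X, y, config = "grnn", k = 5, seed = 3,
                selection = "fold", nSelect = 4)
  expect_equal(rep1@foldSizes, c(64L, 16L))
  expect_gt(cvMetrics(rep1)[["accuracy"]], 90)
  expect_length(cvFolds(rep1), 5L)
  # pooled confusion equals the sum over folds of per-fold counts
  pooled <- Reduce(`+`, cvFolds(rep1))
  expect_equal(sum(pooled), 80)

  # determinism
  rep2 <- runCV(X, y, config = "grnn", k = 5, seed = 3,
                selection = "fold", nSelect = 4)
  expect_identical(cvMetrics(rep1), cvMetrics(rep2))
})

test_that("shuffled labels drive a fast classifier to chance accuracy", {
  set.seed(63)
  X <- rbind(matrix(rnorm(60 * 6), 60),
             matrix(rnorm(60 * 6, mean = 2), 60))
  y <- sample(rep(c("normal", "alcoholic"), each = 60))
  rep0 <- runCV(X, y, config = "grnn", k = 10, seed = 4)
  expect_lt(abs(cvMetrics(rep0)[["accuracy"]] - 50), 15)
})
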