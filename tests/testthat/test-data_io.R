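test_that("UCI-style trial files parse to the matrix written in them", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "0 A 0 0", "0 A 1 1", "0 A 2 2", "0 A 3 3",
               "0 B 0 4", "0 B 1 5", "0 B 2 6", "0 B 3 7"), f)
  rec <- readUciTrial(f)
  expect_equal(unname(signalMatrix(rec)),
               matrix(0:7, nrow = 2, byrow = TRUE))
  expect_equal(channelLabels(rec), c("A", "B"))
  expect_equal(samplingRate(rec), 256)
})

test_that("trial files with only comments or malformed rows are rejected", {
  f <- withr::local_tempfile()
  writeLines(c("# a", "# b"), f)
  expect_error(readUciTrial(f), "no data rows")

  writeLines(c("# ok", "0 A 0 1.5", "0 A broken"), f)
  expect_error(readUciTrial(f), "line 3")

  writeLines(c("0 A 0 1", "0 A 0 2"), f)
  expect_error(readUciTrial(f), "duplicate")
})

test_that("writer output re-reads to an identical recording", {
  rec <- EEGRecording(matrix(round(rnorm(2 * 64), 6), nrow = 2),
                      channelLabels = c("FP1", "FP2"),
                      subjectClass = "alcoholic")
  f <- withr::local_tempfile()
  writeUciTrial(rec, f)
  back <- readUciTrial(f, subjectClass = "alcoholic")
  expect_equal(signalMatrix(back), signalMatrix(rec))
  expect_equal(subjectClass(back), "alcoholic")
})

test_that("segmentation yields floor(n / L) epochs and drops the tail", {
  rec <- function(n) EEGRecording(matrix(seq_len(n), nrow = 1),
                                  subjectClass = "normal")
  expect_length(segmentEpochs(rec(8192), 2048), 4L)
  expect_length(segmentEpochs(rec(2048), 2048), 1L)
  ep <- segmentEpochs(rec(5000), 2048)
  expect_length(ep, 2L)
  expect_length(segmentEpochs(rec(100), 2048), 0L)

  # windows are consecutive: concatenation reproduces the input prefix
  expect_equal(as.vector(t(signalMatrix(ep))), as.numeric(1:4096))
  expect_true(all(epochLabels(ep) == "normal"))
})

test_that("amplitude artifact rule flags and excludes the right epochs", {
  ep <- EpochSet(rbind(c(rep(0, 99), 80), c(rep(0, 99), 50),
                       c(rep(10, 100))),
                 label = "normal")
  flagged <- flagArtifacts(ep)
  expect_equal(artifactFlags(flagged), c(TRUE, FALSE, FALSE))
  expect_length(dropArtifacts(flagged), 2L)

  # idempotent, and raising the threshold never flags more epochs
  expect_equal(artifactFlags(flagArtifacts(flagged)),
               artifactFlags(flagged))
  for (thr in c(40, 60, 79, 81, 120)) {
    lo <- sum(artifactFlags(flagArtifacts(ep, thr)))
    hi <- sum(artifactFlags(flagArtifacts(ep, thr + 10)))
    expect_lte(hi, lo)
  }
})

test_that("spike injection drives the artifact flag", {
  cfg <- synthConfig(spikeRate = 1, seed = 5)
  tr <- generateTrial(cfg, "normal", seed = 5)
  expect_true(artifactFlags(flagArtifacts(tr)))
  cfg0 <- synthConfig(spikeRate = 0, seed = 5)
  tr0 <- generateTrial(cfg0, "normal", seed = 5)
  expect_false(artifactFlags(flagArtifacts(tr0)))
})

test_that("feature CSV round-trips values and labels", {
  vals <- matrix(rnorm(6 * 34), 6)
  fs <- FeatureSet(vals, labels = rep(c("normal", "alcoholic"), 3))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureMatrix(fs, f)
  back <- readFeatureMatrix(f)
  expect_equal(featureMatrix(back), featureMatrix(fs),
               tolerance = 1e-11, ignore_attr = TRUE)
  expect_identical(epochLabels(back), epochLabels(fs))
})

test_that("feature CSV schema violations are reported by column name", {
  vals <- matrix(rnorm(2 * 34), 2)
  fs <- FeatureSet(vals, labels = c("normal", "alcoholic"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureMatrix(fs, f)

  df <- read.csv(f)
  df$label <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  expect_error(readFeatureMatrix(f2), "label")

  df <- read.csv(f, check.names = FALSE)
  df$F35 <- 1
  write.csv(df, f2, row.names = FALSE)
  expect_error(readFeatureMatrix(f2), "F35")
})
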