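# frozen hand-derived cases per feature -------------------------------------

test_that("circle, triangle and vector-length features match hand values", {
  expect_equal(featSCCA(rbind(c(0, 0), c(2, 0))), pi)
  expect_equal(featSCCA(rbind(c(0, 0))), 0)
  expect_equal(featSCCA(rbind(c(0, 0), c(2, 0), c(2, 2))), 2 * pi)

  expect_equal(featSCTA(rbind(c(0, 0), c(1, 0), c(2, 0))), 0)
  expect_equal(featSCTA(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(featSCTA(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))), 1.0)

  expect_equal(featSSVL(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(featSSVL(rbind(c(1, 2))), 0)
  expect_equal(featSSVL(rbind(c(0, 0), c(3, 4), c(3, 4))), 5)
})

test_that("circumcircle features handle right triangles and degeneracy", {
  h <- featHeron(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(h[["SHCA"]], pi / 2)
  expect_equal(h[["SDHC"]], 0)
  expect_equal(h[["SAHC"]], 0)

  expect_equal(unname(featHeron(cbind(0:5, 0))), c(0, 0, 0))

  # complementary right triangles share one circumcircle
  h2 <- featHeron(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(h2[["SDHC"]], 0)
})

test_that("diagonal-line features match the 1/sqrt(2) geometry", {
  expect_equal(featDiag(rbind(c(1, 1), c(2, 2)))[["SH45"]], 0)
  expect_equal(unname(featDiag(rbind(c(1, 0)))), rep(1 / sqrt(2), 2))
  expect_equal(featDiag(rbind(c(1, 0), c(0, 1)))[["SH45"]], sqrt(2))

  expect_equal(featSCRA(rbind(c(1, 0))), 0.5)
  expect_equal(featSCRA(rbind(c(1, 1))), 0)
  expect_equal(featSCRA(rbind(c(2, 0))), 2)
})

test_that("octagon area recovers squares, regular octagons and points", {
  expect_equal(featAOCT(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))), 4)
  th <- (0:7) * pi / 4
  expect_equal(featAOCT(cbind(cos(th), sin(th))), 8 * tan(pi / 8))
  expect_equal(featAOCT(rbind(c(0.3, -0.2))), 0)
})

test_that("origin-referenced features match hand values", {
  expect_equal(featSDTC(rbind(c(3, 4))), 5)
  expect_equal(featSDTC(rbind(c(0, 0))), 0)
  expect_equal(featSDTC(rbind(c(3, 4), c(0, 5))), 10)

  expect_equal(featSATP(rbind(c(0, 0), c(1, 0), c(2, 0))), pi)
  expect_equal(featSATP(rbind(c(0, 0), c(1, 0), c(1, 1))), pi / 2)
  expect_equal(featSATP(rbind(c(0, 0), c(1, 0))), 0)

  expect_equal(featTACR(rbind(c(1, 0), c(0, 1))), 0.5)
  expect_equal(featTACR(rbind(c(1, 1), c(2, 2))), 0)
  expect_equal(featTACR(rbind(c(5, 5))), 0)
})

test_that("dispersion descriptors match closed-form values", {
  cross4 <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(featTDSD(cross4), 2 * sqrt(2 / 3))
  expect_equal(featTDSD(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_equal(featTDSD(rbind(c(1, 1))), 0)

  expect_equal(featELPA(cross4), 2 * pi / 3)
  expect_equal(featELPA(cbind(0:4, 0)), 0)       # collinear
  expect_equal(featELPA(rbind(c(1, 1), c(1, 1))), 0)
})

test_that("central tendency measures count radii against k/20 rings", {
  ctm <- featCTM(cbind(1:10, 0))
  expect_equal(ctm[["CTM1"]], 0)
  expect_equal(ctm[["CTM2"]], 0.1)
  expect_equal(ctm[["CTM19"]], 0.9)

  th <- seq(0, 2 * pi, length.out = 9)[-9]
  onCircle <- featCTM(cbind(cos(th), sin(th)))
  expect_true(all(onCircle == 0))

  expect_true(all(featCTM(matrix(0, 5, 2)) == 1))
})

test_that("the assembled vector has the canonical order and degenerate limit", {
  v <- extractFeatures(cbind(rnorm(20), rnorm(20)))
  expect_identical(names(v), graphicalFeatureNames())

  z <- extractFeatures(matrix(0, 4, 2))
  expect_true(all(z[1:15] == 0))
  expect_true(all(z[16:34] == 1))
})

# oracle equivalence and symmetry properties ---------------------------------

test_that("all 34 features match the brute-force oracle on random clouds", {
  set.seed(30)
  for (rep in 1:25) {
    p <- matrix(rnorm(100, sd = runif(1, 0.5, 5)), 50, 2)
    expect_lt(relErr(unname(extractFeatures(p)), oracleFeatures(p)), 1e-9)
  }
})

test_that("features scale, rotate and permute as their geometry dictates", {
  set.seed(31)
  p <- matrix(rnorm(80), 40, 2)
  v <- extractFeatures(p)
  s <- 2.7
  vs <- extractFeatures(p * s)
  lengthType <- c("SDHC", "SSVL", "SH45", "SH135", "SDTC", "TDSD")
  areaType <- c("SCCA", "SCTA", "SHCA", "AOCT", "TACR", "SCRA", "ELPA")
  invariantType <- c("SAHC", "SATP", sprintf("CTM%d", 1:19))
  expect_equal(vs[lengthType], s * v[lengthType], tolerance = 1e-9)
  expect_equal(vs[areaType], s^2 * v[areaType], tolerance = 1e-9)
  expect_equal(vs[invariantType], v[invariantType], tolerance = 1e-9)

  th <- 0.83
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  vr <- extractFeatures(p %*% Rm)
  rotInvariant <- c("SSVL", "SDTC", "SATP", "ELPA", sprintf("CTM%d", 1:19))
  expect_equal(vr[rotInvariant], v[rotInvariant], tolerance = 1e-8)

  set.seed(32)
  vp <- extractFeatures(p[sample(nrow(p)), ])
  pointSet <- c("SH45", "SH135", "AOCT", "SDTC", "SCRA", "TDSD", "ELPA",
                sprintf("CTM%d", 1:19))
  expect_equal(vp[pointSet], v[pointSet], tolerance = 1e-9)
  orderDep <- c("SCCA", "SCTA", "SSVL", "SATP", "TACR")
  expect_false(all(abs(vp[orderDep] - v[orderDep]) < 1e-9))
})

test_that("CTM values are monotone in the ring index and lie in [0, 1]", {
  set.seed(33)
  for (rep in 1:10) {
    ctm <- featCTM(matrix(rnorm(60), 30, 2))
    expect_true(all(ctm >= 0 & ctm <= 1))
    expect_true(all(diff(ctm) >= 0))
  }
})
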