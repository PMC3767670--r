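test_that("quantization bins [0,255] uniformly into 16 levels", {
  expect_identical(quantize(matrix(0, 1, 2))[1], 0L)
  expect_identical(quantize(matrix(255, 1, 2))[1], 15L)
  expect_identical(quantize(matrix(16, 1, 2))[1], 1L)
  expect_identical(quantize(matrix(15.4, 1, 2))[1], 0L)
  q <- quantize(matrix(77, 4, 4))
  expect_identical(length(unique(as.vector(q))), 1L)
})

test_that("the pooled GLCM matches exhaustive pair enumeration", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2, 2)          # [[0,0],[1,1]] in column form
  expect_equal(computeGLCM(q), oracleGLCM(q))

  set.seed(5)
  for (i in 1:25) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    q <- matrix(sample(0:15, nr * nc, replace = TRUE), nr, nc)
    g <- computeGLCM(q)
    expect_equal(g, oracleGLCM(q))
    expect_equal(sum(g), 1)
    expect_equal(g, t(g))                        # symmetric
    expect_equal(computeGLCM(t(q)), g)           # non-directional pooling
  }
  qc <- quantize(matrix(100, 5, 5))
  gc <- computeGLCM(qc)
  expect_equal(gc[qc[1] + 1, qc[1] + 1], 1)
  expect_error(computeGLCM(matrix(0L, 1, 1)), "at least 2")
})

test_that("Haralick features follow the standard forms and conventions", {
  gConst <- computeGLCM(quantize(matrix(42, 6, 6)))
  f <- glcmFeatures(gConst)
  expect_equal(unname(f), c(0, 0, 1, 1))          # contrast, corr, energy, hom

  chk <- matrix(c(0, 15, 0, 15, 15, 0, 15, 0, 0, 15, 0, 15, 15, 0, 15, 0),
                4, 4) * 1L
  g <- computeGLCM(chk)
  expect_equal(glcmFeatures(g), oracleGlcmFeatures(g))

  set.seed(6)
  for (i in 1:15) {
    q <- matrix(sample(0:15, 36, replace = TRUE), 6, 6)
    g <- computeGLCM(q)
    f <- glcmFeatures(g)
    expect_equal(f, oracleGlcmFeatures(g))
    expect_true(f["energy2"] > 0 && f["energy2"] <= 1)
    expect_true(f["homogeneity"] > 0 && f["homogeneity"] <= 1)
    expect_true(abs(f["correlation"]) <= 1 + 1e-12)
  }
})

test_that("first-order features match a direct moment oracle", {
  f <- firstOrderFeatures(matrix(93, 5, 5))
  expect_equal(unname(f), c(93, 0, 0, 0, 0, 1, 0))

  half <- matrix(c(rep(0, 8), rep(255, 8)), 4, 4)
  f2 <- firstOrderFeatures(half)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["energy"]), 0.5)

  set.seed(8)
  for (i in 1:15) {
    win <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
    expect_equal(firstOrderFeatures(win), oracleFirstOrder(win))
  }
  fz <- firstOrderFeatures(matrix(0, 3, 3))
  expect_equal(unname(fz["cv"]), 0)               # mean-zero convention
})

test_that("region features average over tiled windows as specified", {
  set.seed(9)
  img <- matrix(sample(0:255, 60 * 60, replace = TRUE), 60, 60)
  # region exactly one window
  mask1 <- matrix(FALSE, 60, 60); mask1[11:20, 21:30] <- TRUE
  f1 <- extractRegionFeatures(img, mask1, sizes = 10L)
  expect_equal(as.numeric(f1),
               unname(neuropilScreen:::windowFeatures(img[11:20, 21:30])))

  # three perfectly covered windows: average of the three window oracles
  mask3 <- matrix(FALSE, 60, 60); mask3[5:12, 5:28] <- TRUE
  f3 <- extractRegionFeatures(img, mask3, sizes = 8L)
  wins <- list(img[5:12, 5:12], img[5:12, 13:20], img[5:12, 21:28])
  manual <- rowMeans(vapply(wins, neuropilScreen:::windowFeatures,
                            numeric(11)))
  expect_equal(as.numeric(f3), unname(manual))

  # region smaller than the window in both dimensions: centered fallback
  maskS <- matrix(FALSE, 60, 60); maskS[30:33, 30:33] <- TRUE
  fS <- extractRegionFeatures(img, maskS, sizes = 12L)
  expect_true("centered_fallback" %in% attr(fS, "flag"))
  expect_length(fS, 11L)
})

test_that("the descriptor has 220 canonically named, deterministic entries", {
  expect_length(featureNamesCanonical(), 220L)
  wm <- windowMapCanonical()
  expect_identical(sum(lengths(wm)), 20L)
  expect_identical(names(wm), regionNamesCanonical())

  sec <- generateSection(sectionParams(neuropil_enrichment = 1, seed = 9L))
  fv <- assembleFeatureVector(sec$image, sec$truth$regions)
  expect_length(fv, 220L)
  expect_identical(names(fv), featureNamesCanonical())
  expect_true(all(is.finite(fv)))
  fv2 <- assembleFeatureVector(sec$image, sec$truth$regions)
  expect_identical(fv, fv2)
})

test_that("neuropil features darken with planted enrichment", {
  pHigh <- sectionParams(neuropil_enrichment = 1.5, seed = 13L)
  pZero <- sectionParams(neuropil_enrichment = 0, seed = 13L)
  sHigh <- generateSection(pHigh)
  sZero <- generateSection(pZero)
  fHigh <- assembleFeatureVector(sHigh$image, sHigh$truth$regions)
  fZero <- assembleFeatureVector(sZero$image, sZero$truth$regions)
  for (nm in c("CA1d_w14_mean", "CA3d_w14_mean", "DGd_w14_mean"))
    expect_lt(fHigh[nm], fZero[nm])
})
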