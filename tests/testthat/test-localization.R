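test_that("shape models keep the 8 + 7 convention and bounded modes", {
  model <- modelNoiseFree()
  expect_s4_class(model, "ShapeModel")
  expect_identical(dim(model@meanShape), c(15L, 2L))
  expect_identical(ncol(model@modes), length(model@sdev))
  # shapes sampled at the coefficient bounds stay finite and centered
  for (s in c(-1, 1)) {
    b <- s * model@modeBoundSd * model@sdev
    pts <- shapeFromParams(model, c(0, 0, 0, 1), b)
    expect_true(all(is.finite(pts)))
    expect_equal(colMeans(pts), c(0, 0), tolerance = 1e-8)
  }
  expect_error(buildShapeModel(list(matrix(0, 10, 2))))
})

test_that("the placement energy rewards dark, foreground-dense positions", {
  sec <- cohortNoiseFree()[[1L]]
  pre <- preprocessRoi(sec$image)
  eTruth <- shapeEnergy(pre$image, pre$mask, sec$truth$ahPoints,
                        sec$truth$dgPoints)
  eShift <- shapeEnergy(pre$image, pre$mask, sec$truth$ahPoints + 40,
                        sec$truth$dgPoints + 40)
  expect_lt(eTruth, eShift)
  expect_gte(eTruth, -2)
  expect_lte(eShift, 0)
})

test_that("a degenerate DE run returns the energy of its injected shape", {
  sec <- cohortNoiseFree()[[1L]]
  model <- modelNoiseFree()
  pre <- preprocessRoi(sec$image)
  k <- ncol(model@modes)
  truthPts <- rbind(sec$truth$ahPoints, sec$truth$dgPoints)
  init <- c(colMeans(truthPts), 0, 1, rep(0, k))
  loc <- fitShape(sec$image, model,
                  de = deParams(population = 4L, generations = 0L, seed = 1L),
                  pre = pre,
                  init = matrix(rep(init, each = 4L), 4L))
  pts <- shapeFromParams(model, init[1:4], init[4 + seq_len(k)])
  expect_equal(loc@energy,
               shapeEnergy(pre$image, pre$mask, pts[1:8, ], pts[9:15, ]))
})

test_that("blank sections fail localization cleanly", {
  blank <- matrix(200L, 120, 160)
  loc <- fitShape(blank, modelNoiseFree(), de = deParams(seed = 1L))
  expect_false(loc@success)
  expect_null(controlPoints(loc))
})

test_that("fitted points land on the bands and improve as noise vanishes", {
  model <- modelNoiseFree()
  clean <- generateCohort(0L, 5L, seed = 301L,
                          base_params = sectionParams(noise_sd = 0))
  cleanErr <- vapply(clean, function(sec)
    midlineError(fitShape(sec$image, model, de = deParams(seed = 21L)),
                 sec$truth), numeric(1))
  expect_lt(median(cleanErr), 6)              # band_width at defaults

  # same geometries rendered under heavy noise (paired comparison; mild noise
  # sits below the fit's discretization floor and resolves nothing)
  noisy <- generateCohort(0L, 5L, seed = 301L,
                          base_params = sectionParams(noise_sd = 140))
  noisyErr <- vapply(noisy, function(sec)
    midlineError(fitShape(sec$image, model, de = deParams(seed = 21L)),
                 sec$truth), numeric(1))
  expect_lte(median(cleanErr), median(noisyErr))
})

test_that("atlas registration is exact on self- and translated matches", {
  secs <- generateCohort(0L, 3L, seed = 77L,
                         base_params = sectionParams(noise_sd = 0))
  atlas <- lapply(seq_along(secs), function(i)
    list(level = 140L + 5L * i, image = secs[[i]]$image,
         roi = c(60, 160, 70, 230)))
  # every slice matches itself, never a different slice
  for (i in seq_along(secs)) {
    reg <- registerToAtlas(secs[[i]]$image, atlas,
                           pso = psoParams(seed = 5L))
    expect_false(reg$failed)
    expect_identical(reg$level, atlas[[i]]$level)
  }
  # known translation is recovered within a pixel
  ref <- secs[[1]]$image
  shifted <- matrix(220L, nrow(ref), ncol(ref))
  shifted[6:nrow(ref), 10:ncol(ref)] <-
    ref[1:(nrow(ref) - 5), 1:(ncol(ref) - 9)]
  reg <- registerToAtlas(shifted, atlas[1], pso = psoParams(seed = 5L))
  expect_false(reg$failed)
  expect_lt(abs(reg$transform[5] - 5), 1)
  expect_lt(abs(reg$transform[6] - 9), 1)
})
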