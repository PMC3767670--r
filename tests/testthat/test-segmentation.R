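test_that("area boxes land on their structures and scale equivariantly", {
  seg <- segmentedDefault()
  boxes <- selectAreas(seg$loc)
  expect_identical(boxes$flag, "")
  gt <- seg$section$truth
  H <- nrow(seg$section$image); W <- ncol(seg$section$image)
  boxIoU <- function(box, idx) {
    m <- matrix(FALSE, H, W)
    m[max(1, round(box[1])):min(H, round(box[2])),
      max(1, round(box[3])):min(W, round(box[4]))] <- TRUE
    g <- matrix(FALSE, H, W); g[idx] <- TRUE
    sum(m & g) / sum(m | g)
  }
  gtIdx <- list(
    CA1 = unlist(gt$regions@regions[c("CA1a", "CA1b", "CA1c", "CA1d")]),
    CA3 = unlist(gt$regions@regions[c("CA3a", "CA3b", "CA3c", "CA3d")]),
    DG = unlist(gt$regions@regions[c("DGa", "DGb", "DGc", "DGd", "DGe")]))
  for (nm in names(gtIdx))
    expect_gt(boxIoU(boxes[[nm]], gtIdx[[nm]]), 0.2)

  # doubling the geometry doubles centers and sizes
  loc2 <- new("LocalizationResult", ahPoints = seg$loc@ahPoints * 2,
              dgPoints = seg$loc@dgPoints * 2, energy = seg$loc@energy,
              roi = seg$loc@roi * 2, success = TRUE)
  boxes2 <- selectAreas(loc2)
  for (nm in c("CA1", "CA3", "DG"))
    expect_equal(boxes2[[nm]], boxes[[nm]] * 2, tolerance = 1e-8)
})

test_that("collinear control points trigger the endpoint fallback", {
  ah <- cbind(seq(10, 80, length.out = 8), seq(10, 80, length.out = 8))
  dg <- cbind(seq(20, 60, length.out = 7), seq(60, 20, length.out = 7))
  loc <- new("LocalizationResult", ahPoints = ah, dgPoints = dg,
             energy = -1, roi = c(1, 100, 1, 100), success = TRUE)
  boxes <- selectAreas(loc)
  expect_identical(boxes$flag, "collinear")
})

test_that("accepted partitions have exactly 13 disjoint nonempty regions", {
  regs <- segmentedDefault()$regions
  expect_s4_class(regs, "RegionSet")
  expect_identical(regionNames(regs), regionNamesCanonical())
  sizes <- vapply(regs@regions, length, integer(1))
  expect_true(all(sizes > 0))
  expect_false(anyDuplicated(unlist(regs@regions)) > 0)
})

test_that("band cores sit on the true bands; neuropil strips avoid them", {
  sec <- cohortNoiseFree()[[1L]]
  model <- modelNoiseFree()
  loc <- fitShape(sec$image, model, de = deParams(seed = 31L))
  regs <- partitionRegions(selectAreas(loc), sec$image,
                           inward = colMeans(controlPoints(loc)))
  expect_s4_class(regs, "RegionSet")
  band <- which(sec$truth$bandMask)
  for (nm in c("CA1a", "CA3a", "DGa"))
    expect_gt(mean(regs@regions[[nm]] %in% band), 0.8)
  for (nm in c("CA1d", "CA3d", "DGd", "DGe"))
    expect_identical(sum(regs@regions[[nm]] %in% band), 0L)
})

test_that("partition fails cleanly on blank areas", {
  blank <- matrix(200L, 200, 280)
  boxes <- list(CA1 = c(10, 60, 10, 60), CA3 = c(10, 60, 80, 130),
                DG = c(80, 130, 10, 60), flag = "")
  out <- partitionRegions(boxes, blank, inward = c(100, 140))
  expect_true(segmentationFailed(out))
  expect_match(out$reason, "empty band")
})

test_that("QC samples 72 points and separates good from shifted partitions", {
  f <- forestsDefault()
  seg <- segmentedDefault()
  qc <- qcSegmentation(seg$section$image, seg$regions, f$inside, f$accept,
                       seed = 6L)
  expect_identical(qc$n_points, 72L)
  expect_true(qc$accepted)
  expect_identical(nrow(qc$region_stats), 13L)

  # a perfect (ground-truth) segmentation classifies nearly all probe points
  qcGT <- qcSegmentation(seg$section$image, seg$section$truth$regions,
                         f$inside, f$accept, seed = 6L)
  expect_gte(qcGT$point_accuracy, 0.9)
  expect_true(qcGT$accepted)

  bw <- seg$section$truth$params$band_width
  bad <- neuropilScreen:::shiftRegionSet(seg$regions, 3L * bw, 3L * bw)
  qcBad <- qcSegmentation(seg$section$image, bad, f$inside, f$accept,
                          seed = 6L)
  expect_false(qcBad$accepted)
  expect_error(qcSegmentation(seg$section$image, seg$regions, NULL, NULL),
               "trained")
})

test_that("QC rarely accepts planted failures across the cohort", {
  f <- forestsDefault()
  coh <- cohortDefault()
  accepts <- vapply(seq_along(coh), function(i) {
    sec <- coh[[i]]
    bw <- sec$truth$params$band_width
    bad <- neuropilScreen:::shiftRegionSet(sec$truth$regions, 3L * bw,
                                           3L * bw)
    qcSegmentation(sec$image, bad, f$inside, f$accept,
                   seed = 100L + i)$accepted
  }, logical(1))
  expect_lt(mean(accepts), 0.1)
})

test_that("series retry starts at level 145 and walks outward", {
  f <- forestsDefault()
  coh <- cohortDefault()
  model <- shapeModelFromCohort(coh)
  good <- coh[[2L]]$image
  blank <- matrix(210L, nrow(good), ncol(good))

  # an acceptable default level is used without trying others
  res <- processSeries(list(list(image = good, level = 145L),
                            list(image = good, level = 144L)),
                       model, f$inside, f$accept, de = deParams(seed = 41L),
                       seed = 42L)
  expect_false(res$discarded)
  expect_identical(res$atlas_level, 145L)
  expect_identical(res$attempts, 1L)
  expect_s4_class(res$regions, "RegionSet")

  # only level 131 can pass: retry walks to it
  res2 <- processSeries(list(list(image = blank, level = 145L),
                             list(image = good, level = 131L),
                             list(image = blank, level = 129L)),
                        model, f$inside, f$accept, de = deParams(seed = 41L),
                        seed = 42L)
  expect_false(res2$discarded)
  expect_identical(res2$atlas_level, 131L)

  # blank everywhere: gene discarded with a reason
  res3 <- processSeries(list(list(image = blank, level = 145L)),
                        model, f$inside, f$accept, de = deParams(seed = 41L),
                        seed = 42L)
  expect_true(res3$discarded)
  expect_true(nzchar(res3$reason))
  expect_true(processSeries(list(), model, f$inside, f$accept)$discarded)
  expect_error(processSeries(list(list(image = good, level = 200L)),
                             model, f$inside, f$accept), "117")
})
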