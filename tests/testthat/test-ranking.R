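test_that("the expression filter applies strict OR semantics", {
  md <- data.frame(probe = paste0("p", 1:6),
                   expression_level = c(25, 20, 0, 19, 21, 0),
                   expression_density = c(5, 20, 30, 19, 0, 0))
  kept <- expressionFilter(md)
  expect_identical(kept, c("p1", "p3", "p5"))

  mdNA <- data.frame(probe = c("a", "b"),
                     expression_level = c(NA, 50),
                     expression_density = c(NA, NA))
  expect_warning(kept2 <- expressionFilter(mdNA), "excluded")
  expect_identical(kept2, "b")
})

test_that("pearson matches a direct-formula oracle and flags degeneracy", {
  expect_equal(as.numeric(pearson(1:5, 1:5)), 1)
  expect_equal(as.numeric(pearson(1:5, -(1:5))), -1)

  x <- c(2, 4, 1, 7, 5); y <- c(1, 3, 2, 9, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(as.numeric(pearson(x, y)), oracle)

  r0 <- pearson(rep(3, 4), 1:4)
  expect_identical(as.numeric(r0), 0)
  expect_identical(attr(r0, "flag"), "zero_variance")
})

test_that("the prototype scores itself at r = 1, rank 1", {
  ts <- plantedTrainingSet(nNoise = 10L, seed = 23L)
  mask <- rep(c(TRUE, FALSE), c(5L, 7L))
  proto <- prototypeVector(ts, mask)
  protoRaw <- proto$center + proto$scale * proto$values
  feats <- rbind(self = protoRaw,
                 other = protoRaw + c(3, -2, 1, 4, -1))
  colnames(feats) <- proto$features
  tab <- rankGenes(feats, proto)
  expect_equal(tab$r[tab$probe == "self"], 1)
  expect_identical(tab$rank[tab$probe == "self"], 1L)
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$r) <= 0))
})

test_that("ranking breaks ties by probe id and respects affine rescaling", {
  ts <- plantedTrainingSet(nNoise = 6L, seed = 24L)
  mask <- rep(TRUE, 8L)
  proto <- prototypeVector(ts, mask)
  set.seed(1)
  row <- rnorm(8)
  feats <- rbind(bbb = row, aaa = row)
  colnames(feats) <- proto$features
  tab <- rankGenes(feats, proto)
  expect_identical(tab$probe, c("aaa", "bbb"))

  # rescale one feature consistently in training and screen: r unchanged
  X2 <- ts$X
  X2[, 3] <- X2[, 3] * 50 + 7
  ts2 <- trainingSet(X2, ts$labels)
  proto2 <- prototypeVector(ts2, mask)
  feats2 <- feats
  feats2[, 3] <- feats2[, 3] * 50 + 7
  expect_equal(rankGenes(feats2, proto2)$r, tab$r)

  expect_error(rankGenes(feats[, 1:3], proto), "lacks selected")
})

test_that("graded planted enrichment is recovered in the ranking", {
  screen <- generateScreen(12L, e_range = c(0, 2), seed = 61L)
  coh <- cohortDefault()
  feats <- t(vapply(screen, function(s)
    assembleFeatureVector(s$image, s$truth$regions), numeric(220L)))
  rownames(feats) <- vapply(screen, `[[`, character(1), "id")
  trainX <- t(vapply(coh, function(s)
    assembleFeatureVector(s$image, s$truth$regions), numeric(220L)))
  rownames(trainX) <- vapply(coh, `[[`, character(1), "id")
  ts <- trainingSet(trainX, vapply(coh, `[[`, character(1), "label"))
  dd <- dedupFeatures(ts)
  tsR <- trainingSet(ts$X[, dd$kept], ts$labels)
  cs <- consensusSelect(tsR, gaParams(generations = 60L, runs = 5L,
                                      seed = 62L))
  proto <- prototypeVector(tsR, cs$selected)
  tab <- rankGenes(feats, proto)
  e <- vapply(screen, `[[`, numeric(1), "enrichment")
  names(e) <- rownames(feats)
  expect_gt(cor(e[tab$probe], tab$r, method = "spearman"), 0.8)
})

test_that("stability summaries expose corrupted sections, not medians", {
  ident <- list(g1 = rep(0.9, 6))
  tab <- stabilityProfile(ident)
  expect_equal(tab$iqr, 0)

  mixed <- list(g2 = c(0.88, 0.9, 0.91, 0.89, 0.9, 0.1))
  tab2 <- stabilityProfile(mixed)
  expect_lt(tab2$min, tab2$median - 0.5)
  expect_gt(tab2$median, 0.85)

  single <- stabilityProfile(list(g3 = 0.7))
  expect_identical(single$flag, "single_section")
})

test_that("high-enrichment genes score stably across jittered geometry", {
  coh <- cohortDefault()
  trainX <- t(vapply(coh, function(s)
    assembleFeatureVector(s$image, s$truth$regions), numeric(220L)))
  rownames(trainX) <- vapply(coh, `[[`, character(1), "id")
  ts <- trainingSet(trainX, vapply(coh, `[[`, character(1), "label"))
  dd <- dedupFeatures(ts)
  tsR <- trainingSet(ts$X[, dd$kept], ts$labels)
  cs <- consensusSelect(tsR, gaParams(generations = 60L, runs = 3L,
                                      seed = 63L))
  proto <- prototypeVector(tsR, cs$selected)

  base <- sectionParams(neuropil_enrichment = 1.5)
  rs <- vapply(1:6, function(i) {
    p <- base
    p$seed <- deriveSeed(64L, i)
    p <- withr::with_seed(deriveSeed(65L, i),
                          neuropilScreen:::jitterGeometry(p))
    s <- generateSection(p)
    fv <- assembleFeatureVector(s$image, s$truth$regions)
    tab <- rankGenes(matrix(fv, 1L, dimnames = list("g", names(fv))), proto)
    tab$r
  }, numeric(1))
  prof <- stabilityProfile(list(gene = rs))
  expect_lt(prof$iqr, 0.15)
})
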