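test_that("near-duplicate features collapse to a single representative", {
  set.seed(10)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 2] <- X[, 1]                      # exact duplicate
  X[, 4] <- 1.0001 * X[, 3]             # affine duplicate, r = 1
  colnames(X) <- paste0("f", 1:6)
  ts <- trainingSet(X, rep(c("positive", "negative"), c(3, 17)))
  dd <- dedupFeatures(ts)
  expect_false("f2" %in% dd$kept)
  expect_identical(unname(dd$dropped["f2"]), "f1")
  expect_false("f4" %in% dd$kept)
  expect_identical(unname(dd$dropped["f4"]), "f3")
  expect_true(all(c("f1", "f3", "f5", "f6") %in% dd$kept))
})

test_that("independent features all survive dedup; zero variance collapses", {
  set.seed(11)
  repeat {                               # draw until pairwise |r| < 0.9
    X <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("f", 1:8)))
    cm <- abs(cor(X)); diag(cm) <- 0
    if (max(cm) < 0.9) break
  }
  ts <- trainingSet(X, rep(c("positive", "negative"), c(3, 17)))
  expect_identical(dedupFeatures(ts)$kept, colnames(X))

  Xz <- cbind(X, z1 = rep(2, 20), z2 = rep(-5, 20))
  tsz <- trainingSet(Xz, rep(c("positive", "negative"), c(3, 17)))
  ddz <- dedupFeatures(tsz)
  expect_true("z1" %in% ddz$kept)
  expect_identical(unname(ddz$dropped["z2"]), "z1")
})

test_that("the silhouette matches the hand-computed 4-point fixture", {
  X <- matrix(c(0, 1, 10, 11), 4, 1, dimnames = list(NULL, "f1"))
  ts <- list(X = X, labels = rep(c("positive", "negative"), each = 2))
  class(ts) <- "TrainingSet"
  # s(0) = (10.5-1)/10.5, s(1) = (9.5-1)/9.5, symmetric for the other group
  manual <- (2 * (9.5 / 10.5) + 2 * (8.5 / 9.5)) / 4
  expect_equal(silhouetteFitness(TRUE, ts), manual, tolerance = 1e-12)
})

test_that("silhouette fitness is bounded, invariant and convention-ruled", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10, sd = 0.3), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  X[1:3, ] <- X[1:3, ] + 12              # tight, well-separated positives
  labs <- rep(c("positive", "negative"), c(3, 17))
  ts <- trainingSet(X, labs)
  f <- silhouetteFitness(rep(TRUE, 10), ts)
  expect_gt(f, 0.9)
  expect_lte(f, 1)

  perm <- sample(20)
  tsPerm <- trainingSet(X[perm, ], labs[perm])
  expect_equal(silhouetteFitness(rep(TRUE, 10), tsPerm), f)

  tsShift <- trainingSet(X + 100, labs)  # constant offset, z-scored away
  expect_equal(silhouetteFitness(rep(TRUE, 10), tsShift), f)

  expect_identical(silhouetteFitness(rep(FALSE, 10), ts), -1)

  Xsame <- matrix(1, 20, 2, dimnames = list(NULL, c("a", "b")))
  tsSame <- trainingSet(Xsame, labs)
  expect_identical(silhouetteFitness(c(TRUE, TRUE), tsSame), 0)
})

test_that("null-data silhouette stays near zero", {
  set.seed(13)
  f <- replicate(100, {
    X <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(NULL, paste0("f", 1:15)))
    ts <- trainingSet(X, rep(c("positive", "negative"), c(3, 17)))
    silhouetteFitness(rep(TRUE, 15), ts)
  })
  expect_true(all(abs(f) < 0.2))
})

test_that("GA runs are deterministic, elitist and find planted structure", {
  ts <- plantedTrainingSet(nNoise = 30L, seed = 21L)
  ga <- gaParams(generations = 60L)
  m1 <- gaRun(ts, ga, run_seed = 5L)
  m2 <- gaRun(ts, ga, run_seed = 5L)
  expect_identical(m1, m2)

  m0 <- gaRun(ts, gaParams(generations = 0L), run_seed = 5L)
  expect_gte(m1$fitness, m0$fitness)     # best-so-far never decreases

  planted <- c(TRUE, TRUE, rep(FALSE, 30))
  expect_gte(m1$fitness, 0.99 * silhouetteFitness(planted, ts))
  expect_true(any(m1$bits[1:2]))   # full-length runs recover both (see
                                   # the acceptance suite); a short run must
                                   # at least latch onto the planted signal
})

test_that("consensus with one run equals that run and never goes empty", {
  ts <- plantedTrainingSet(nNoise = 20L, seed = 22L)
  ga1 <- gaParams(generations = 40L, runs = 1L, seed = 31L)
  cs <- consensusSelect(ts, ga1)
  single <- gaRun(ts, ga1, run_seed = deriveSeed(31L, 8001L))
  expect_identical(unname(cs$selected), single$bits)
  expect_identical(cs$threshold_runs, 1L)
  expect_true(any(cs$selected))
})
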