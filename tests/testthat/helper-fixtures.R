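# Shared fixtures, built once per test run and cached lazily so single-file
# runs only pay for what they use.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# small noise-free labeled cohort (localization / segmentation tests)
cohortNoiseFree <- function() fixture("cohortNF", function()
  generateCohort(3L, 5L, seed = 301L,
                 base_params = sectionParams(noise_sd = 0)))

# noisy cohort at defaults (QC forest training)
cohortDefault <- function() fixture("cohortDef", function()
  generateCohort(3L, 7L, seed = 302L))

shapeModelFromCohort <- function(cohort)
  buildShapeModel(lapply(cohort, function(s)
    rbind(s$truth$ahPoints, s$truth$dgPoints)))

modelNoiseFree <- function() fixture("modelNF", function()
  shapeModelFromCohort(cohortNoiseFree()))

forestsDefault <- function() fixture("forestsDef", function() {
  coh <- cohortDefault()
  rfI <- trainInsideForest(coh, seed = 303L)
  list(inside = rfI, accept = trainAcceptForest(coh, rfI, seed = 304L))
})

# one good fitted segmentation of the first default-cohort section
segmentedDefault <- function() fixture("segDef", function() {
  coh <- cohortDefault()
  model <- shapeModelFromCohort(coh)
  sec <- coh[[1L]]
  loc <- fitShape(sec$image, model, de = deParams(seed = 305L))
  regions <- partitionRegions(selectAreas(loc), sec$image,
                              inward = colMeans(controlPoints(loc)))
  list(section = sec, loc = loc, regions = regions)
})

# exhaustive pair-enumeration GLCM oracle (independent of computeGLCM)
oracleGLCM <- function(q, levels = 16L) {
  counts <- matrix(0, levels, levels)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    for (off in offs) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        a <- q[r, c] + 1L; b <- q[r2, c2] + 1L
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

# direct-formula Haralick oracle over explicit double loops
oracleGlcmFeatures <- function(g) {
  L <- nrow(g)
  contrast <- 0; energy <- 0; homogeneity <- 0
  mui <- 0; muj <- 0
  for (i in 1:L) for (j in 1:L) {
    mui <- mui + (i - 1) * g[i, j]
    muj <- muj + (j - 1) * g[i, j]
  }
  vi <- 0; vj <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- g[i, j]
    contrast <- contrast + p * ((i - 1) - (j - 1))^2
    energy <- energy + p^2
    homogeneity <- homogeneity + p / (1 + abs(i - j))
    vi <- vi + p * ((i - 1) - mui)^2
    vj <- vj + p * ((j - 1) - muj)^2
    cov <- cov + p * ((i - 1) - mui) * ((j - 1) - muj)
  }
  corr <- if (vi * vj == 0) 0 else cov / sqrt(vi * vj)
  c(contrast = contrast, correlation = corr, energy2 = energy,
    homogeneity = homogeneity)
}

# brute-force Otsu oracle: try all 256 thresholds on the raw pixels
oracleOtsu <- function(image) {
  v <- as.integer(round(image))
  best <- -Inf; bestT <- NA_integer_
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) {
      best <- sb
      bestT <- t
    }
  }
  bestT
}

# direct first-order moment oracle on raw intensities
oracleFirstOrder <- function(win) {
  v <- as.numeric(win)
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  s <- sqrt(m2)
  h <- rep(0, 16)
  for (x in v) {
    b <- min(floor(round(x) / 16), 15) + 1
    h[b] <- h[b] + 1
  }
  h <- h / n
  ent <- -sum(h[h > 0] * log2(h[h > 0]))
  c(mean = m, sd = s, cv = if (m == 0) 0 else s / m,
    skewness = if (s == 0) 0 else m3 / m2^1.5,
    kurtosis = if (s == 0) 0 else m4 / m2^2,
    energy = sum(h^2), entropy = ent)
}

# mean distance of fitted control points to the true band midlines
midlineError <- function(loc, truth, n = 400L) {
  fitted <- controlPoints(loc)
  dense <- rbind(neuropilScreen:::curvePoints(truth$params$ah_curve, n),
                 neuropilScreen:::curvePoints(truth$params$dg_curve, n))
  mean(vapply(seq_len(nrow(fitted)), function(i)
    sqrt(min((dense[, 1] - fitted[i, 1])^2 +
             (dense[, 2] - fitted[i, 2])^2)), numeric(1)))
}

# training matrix with two planted separating features among Gaussian noise
plantedTrainingSet <- function(nNoise = 100L, seed = 42L, shift = 6) {
  set.seed(seed)
  p <- nNoise + 2L
  X <- matrix(rnorm(20 * p), 20, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  X[1:3, 1] <- X[1:3, 1] + shift
  X[1:3, 2] <- X[1:3, 2] - shift
  trainingSet(X, rep(c("positive", "negative"), c(3L, 17L)))
}
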