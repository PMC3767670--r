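#' @include AllClasses.R utils.R
NULL

#' Per-region window sizes of the texture descriptor
#'
#' Band-core regions (a) and the outer DG neuropil (DGe) are described at two
#' window sizes (18 and 36), band flanks (b, c) at 24, and the near neuropil
#' strips (d) at 14 and 28. 20 (region, window) pairs x 11 features = 220.
#'
#' @return named list mapping each of the 13 regions to its window sizes.
#' @export
windowMapCanonical <- function() {
  list(CA1a = c(18L, 36L), CA1b = 24L, CA1c = 24L, CA1d = c(14L, 28L),
       CA3a = c(18L, 36L), CA3b = 24L, CA3c = 24L, CA3d = c(14L, 28L),
       DGa = c(18L, 36L), DGb = 24L, DGc = 24L, DGd = c(14L, 28L),
       DGe = c(18L, 36L))
}

# the 11 per-window features in canonical order
featureKinds <- function() {
  c("mean", "sd", "cv", "skewness", "kurtosis", "energy", "entropy",
    "contrast", "correlation", "energy2", "homogeneity")
}

#' Canonical names of the 220 texture features
#'
#' Order: regions in canonical order, window sizes ascending within a region,
#' the 7 first-order then 4 second-order features within a window
#' (e.g. \code{CA1a_w18_mean}).
#'
#' @return character vector of length 220.
#' @export
featureNamesCanonical <- function() {
  wm <- windowMapCanonical()
  unlist(lapply(names(wm), function(rg)
    unlist(lapply(wm[[rg]], function(s)
      paste0(rg, "_w", s, "_", featureKinds())))), use.names = FALSE)
}

#' Quantize an 8-bit window to 16 gray levels
#'
#' Uniform binning of [0, 255]: level = floor(v / 16), clamped to 15.
#'
#' @param window matrix in [0, 255].
#' @param levels number of levels (fixed at 16 in the pipeline).
#' @return integer matrix of levels in [0, levels - 1].
#' @export
quantize <- function(window, levels = 16L) {
  q <- pmin(floor(round(window) / (256L / levels)), levels - 1L)
  matrix(as.integer(q), nrow(window), ncol(window))
}

#' Pooled symmetric non-directional GLCM
#'
#' Counts co-occurrences of quantized levels over the four unit-distance
#' directions (0,1), (1,0), (1,1), (1,-1), counts each pair in both orders
#' (symmetric), pools the directions and normalizes to sum 1.
#'
#' @param window quantized window from \code{\link{quantize}}.
#' @param levels number of gray levels (16).
#' @return levels x levels matrix summing to 1, symmetric.
#' @export
computeGLCM <- function(window, levels = 16L) {
  nr <- nrow(window); nc <- ncol(window)
  if (nr < 2L && nc < 2L)
    stop("window must be at least 2 pixels in one direction")
  counts <- matrix(0, levels, levels)
  addPairs <- function(a, b) {
    if (length(a) == 0L) return()
    idx <- a * levels + b + 1L
    counts <<- counts + matrix(tabulate(idx, nbins = levels * levels),
                               levels, levels, byrow = TRUE)
  }
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r0) < 1L || length(c0) < 1L) next
    a <- window[r0, c0, drop = FALSE]
    b <- window[r0 + dr, c0 + dc, drop = FALSE]
    addPairs(as.integer(a), as.integer(b))
    addPairs(as.integer(b), as.integer(a))
  }
  tot <- sum(counts)
  if (tot == 0) stop("no valid co-occurrence pairs in window")
  counts / tot
}

#' Haralick features of a normalized GLCM
#'
#' Contrast, correlation, energy (angular second moment) and homogeneity
#' (inverse difference moment). Correlation of a constant window (zero
#' marginal SD) is defined as 0.
#'
#' @param g normalized GLCM from \code{\link{computeGLCM}}.
#' @return named numeric: contrast, correlation, energy2, homogeneity.
#' @export
glcmFeatures <- function(g) {
  L <- nrow(g)
  lev <- 0:(L - 1)
  ii <- matrix(lev, L, L)
  jj <- t(ii)
  pi_ <- rowSums(g); pj <- colSums(g)
  mui <- sum(lev * pi_); muj <- sum(lev * pj)
  si <- sqrt(sum((lev - mui)^2 * pi_))
  sj <- sqrt(sum((lev - muj)^2 * pj))
  corr <- if (si * sj == 0) 0 else
    sum(g * (ii - mui) * (jj - muj)) / (si * sj)
  c(contrast = sum(g * (ii - jj)^2),
    correlation = corr,
    energy2 = sum(g^2),
    homogeneity = sum(g / (1 + abs(ii - jj))))
}

#' First-order features of a raw-intensity window
#'
#' Mean, standard deviation, coefficient of variation (0 when the mean is 0),
#' population skewness and kurtosis (0 when the SD is 0), and energy/entropy
#' of the 16-bin normalized intensity histogram (entropy in bits, 0 log 0 = 0).
#'
#' @param window matrix in [0, 255] (raw intensities, not quantized).
#' @return named numeric of length 7.
#' @export
firstOrderFeatures <- function(window) {
  v <- as.numeric(window)
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  s <- sqrt(m2)
  cv <- if (m == 0) 0 else s / m
  skw <- if (s == 0) 0 else mean((v - m)^3) / m2^1.5
  krt <- if (s == 0) 0 else mean((v - m)^4) / m2^2
  h <- tabulate(pmin(floor(round(v) / 16), 15) + 1L, nbins = 16L) / n
  hp <- h[h > 0]
  c(mean = m, sd = s, cv = cv, skewness = skw, kurtosis = krt,
    energy = sum(h^2), entropy = -sum(hp * log2(hp)))
}

# all 11 features of one raw window
windowFeatures <- function(window) {
  c(firstOrderFeatures(window), glcmFeatures(computeGLCM(quantize(window))))
}

#' Average texture features over windows covering a region
#'
#' The region's bounding box is tiled with non-overlapping size x size windows
#' anchored at its top-left corner; windows with at least half of their pixels
#' inside the mask are kept and the 11 features are averaged across them. When
#' no window passes the coverage rule the single best-covered window is used;
#' when the region is smaller than the window in both dimensions one window is
#' centered on the region centroid (flagged).
#'
#' @param image section image, [0, 255].
#' @param mask logical matrix (the region), same dimension as image.
#' @param sizes window sizes to evaluate.
#' @param minCoverage in-mask fraction required to keep a window (0.5).
#' @return named numeric, 11 features per size (names \code{w<size>_<feat>}),
#'   with attribute "flag" when a fallback was taken.
#' @export
extractRegionFeatures <- function(image, mask, sizes, minCoverage = 0.5) {
  stopifnot(any(mask))
  H <- nrow(image); W <- ncol(image)
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  flag <- character()
  out <- lapply(sizes, function(s) {
    wins <- list()
    if (r1 - r0 + 1 >= s || c1 - c0 + 1 >= s) {
      rows <- seq(r0, max(r0, r1 - s + 1L), by = s)
      cols <- seq(c0, max(c0, c1 - s + 1L), by = s)
      for (rr in rows) for (cc in cols) {
        if (rr + s - 1L > H || cc + s - 1L > W) next
        wins[[length(wins) + 1L]] <- c(rr, cc)
      }
    }
    if (length(wins)) {
      cov <- vapply(wins, function(w)
        mean(mask[w[1]:(w[1] + s - 1L), w[2]:(w[2] + s - 1L)]), numeric(1))
      keep <- wins[cov >= minCoverage]
      if (!length(keep)) {
        keep <- wins[which.max(cov)]
        flag <<- union(flag, "best_covered_fallback")
      }
    } else {
      ctr <- round(colMeans(idx))
      rr <- clamp(ctr[1] - s %/% 2L, 1L, max(1L, H - s + 1L))
      cc <- clamp(ctr[2] - s %/% 2L, 1L, max(1L, W - s + 1L))
      keep <- list(c(rr, cc))
      flag <<- union(flag, "centered_fallback")
    }
    fmat <- vapply(keep, function(w)
      windowFeatures(image[w[1]:(w[1] + min(s, H) - 1L),
                           w[2]:(w[2] + min(s, W) - 1L)]),
      numeric(11L))
    fv <- rowMeans(matrix(fmat, nrow = 11L))
    names(fv) <- featureKinds()
    setNames(fv, paste0("w", s, "_", names(fv)))
  })
  res <- unlist(out)
  attr(res, "flag") <- flag
  res
}

#' Assemble the 220-dimensional texture descriptor of a section
#'
#' Applies \code{\link{extractRegionFeatures}} with the canonical window map
#' to every region of an accepted \code{\linkS4class{RegionSet}} and emits the
#' features in canonical order.
#'
#' @param image section image, [0, 255].
#' @param regions a \code{\linkS4class{RegionSet}} with 13 nonempty regions.
#' @param windowMap window map (default \code{\link{windowMapCanonical}}).
#' @return named numeric vector of length 220.
#' @export
assembleFeatureVector <- function(image, regions,
                                  windowMap = windowMapCanonical()) {
  assertGrayImage(image)
  stopifnot(is(regions, "RegionSet"))
  vals <- lapply(names(windowMap), function(rg) {
    ix <- regions@regions[[rg]]
    if (is.null(ix) || length(ix) == 0L)
      stop("region ", rg, " is missing or empty")
    fv <- extractRegionFeatures(image, regionMask(regions, rg),
                                windowMap[[rg]])
    setNames(as.numeric(fv), paste0(rg, "_", names(fv)))
  })
  out <- unlist(vals)
  stopifnot(identical(names(out), featureNamesCanonical()))
  out
}
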