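#' @include AllClasses.R localize.R
NULL

#' Segmentation-failure signal
#'
#' Returned instead of a \code{\linkS4class{RegionSet}} when an area cannot be
#' partitioned (blank box, empty band, empty region); carries the reason.
#' Test with \code{segmentationFailed()}.
#'
#' @param x object to test.
#' @return \code{segmentationFailed} returns TRUE for a failure signal.
#' @export
segmentationFailed <- function(x) inherits(x, "segmentationFailure")

segFailure <- function(reason)
  structure(list(reason = reason), class = "segmentationFailure")

# unsigned turn angle at interior vertices of a polyline
turnAngles <- function(pts) {
  n <- nrow(pts)
  u <- pts[2:(n - 1), , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  v <- pts[3:n, , drop = FALSE] - pts[2:(n - 1), , drop = FALSE]
  cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  dot <- u[, 1] * v[, 1] + u[, 2] * v[, 2]
  abs(atan2(cross, dot))
}

squareBox <- function(center, size) {
  h <- size / 2
  c(center[1] - h, center[1] + h, center[2] - h, center[2] + h)
}

#' Select the CA1, CA3 and DG areas of interest
#'
#' Places three square boxes from the fitted control points: on the
#' maximum-curvature locus of the CA1 half of the AH chain (the first
#' points), on that of the CA3 half, and on the midpoint of the medial half
#' of the DG polyline. The locus is the curvature-weighted centroid of the
#' half's interior points, which is robust when the discrete turn angles are
#' nearly tied along a smooth bend. Box sides are proportional to the mean
#' inter-point spacing, so the construction is scale-equivariant. Degenerate
#' (collinear) chains fall back to near-end points and set a flag.
#'
#' @param loc a successful \code{\linkS4class{LocalizationResult}}.
#' @param boxScale AH box side as a multiple of the mean AH point spacing.
#' @param dgBoxScale DG box side as a multiple of the mean DG point spacing;
#'   larger than \code{boxScale} because DG segments are shorter while the box
#'   must still hold the band, both neuropil strips and the largest (36 px)
#'   texture window.
#' @return \code{list(CA1, CA3, DG, flag)}; boxes are c(row0, row1, col0,
#'   col1), not clamped to any image.
#' @export
selectAreas <- function(loc, boxScale = 1.5, dgBoxScale = 2.8) {
  stopifnot(is(loc, "LocalizationResult"), loc@success)
  ah <- loc@ahPoints; dg <- loc@dgPoints
  ang <- turnAngles(ah)              # angles at interior points 2..7
  flag <- ""
  nA <- length(ang)
  half1 <- seq_len(nA %/% 2)         # interior points of the CA1 half
  half3 <- setdiff(seq_len(nA), half1)
  if (max(ang) < 1e-3) {
    flag <- "collinear"
    cCA1 <- ah[2L, ]; cCA3 <- ah[nrow(ah) - 1L, ]
  } else {
    wcent <- function(cand) {
      w <- ang[cand] / sum(ang[cand])
      colSums(ah[cand + 1L, , drop = FALSE] * w)
    }
    cCA1 <- wcent(half1)
    cCA3 <- wcent(half3)
  }
  spacingAH <- mean(sqrt(diff(ah[, 1])^2 + diff(ah[, 2])^2))
  spacingDG <- mean(sqrt(diff(dg[, 1])^2 + diff(dg[, 2])^2))
  # midpoint of the medial half: arc-length position 3/4 along the DG chain
  dgMid <- samplePolyline(dg, 5L)[4L, ]
  list(CA1 = squareBox(cCA1, boxScale * spacingAH),
       CA3 = squareBox(cCA3, boxScale * spacingAH),
       DG = squareBox(dgMid, dgBoxScale * spacingDG),
       flag = flag)
}

# partition one box into band core (a), flanks (b, c) and neuropil strips
# (d and, for the DG, e); returns full-image linear indices or NULL
partitionOneBox <- function(box, image, inward, withOuter) {
  H <- nrow(image); W <- ncol(image)
  r0 <- clamp(round(box[1]), 1, H); r1 <- clamp(round(box[2]), 1, H)
  c0 <- clamp(round(box[3]), 1, W); c1 <- clamp(round(box[4]), 1, W)
  if (r1 - r0 < 4 || c1 - c0 < 4) return(NULL)
  crop <- image[r0:r1, c0:c1]
  seg <- otsuSegment(crop)
  if (attr(seg, "flag") == "constant" || !any(seg)) return(NULL)
  band <- keepLargestComponents(seg, k = 1L)
  bp <- which(band, arr.ind = TRUE)
  if (nrow(bp) < 8) return(NULL)
  ctr <- colMeans(bp)
  pc <- prcomp(bp, center = TRUE)
  u <- pc$rotation[, 1]; nv <- pc$rotation[, 2]
  # orient the normal toward the curve interior (neuropil side)
  inwardLocal <- inward - c(r0 - 1, c0 - 1)
  if (sum((inwardLocal - ctr) * nv) < 0) nv <- -nv

  aBand <- sweep(bp, 2, ctr) %*% u
  amin <- min(aBand); amax <- max(aBand); L <- amax - amin
  if (L <= 0) return(NULL)
  h <- quantile(abs(sweep(bp, 2, ctr) %*% nv), 0.98, names = FALSE) + 1

  rr <- rep(r0:r1, times = c1 - c0 + 1)
  cc <- rep(c0:c1, each = r1 - r0 + 1)
  rel <- cbind(rr - (r0 - 1) - ctr[1], cc - (c0 - 1) - ctr[2])
  aAll <- rel %*% u
  qAll <- rel %*% nv
  inBand <- as.logical(band)
  inAx <- aAll >= amin & aAll <= amax
  strip <- function(sgn) {
    qs <- sgn * qAll
    !inBand & inAx & qs > h & qs <= 3 * h
  }
  out <- list(
    a = inBand & aAll >= amin + 0.25 * L & aAll <= amin + 0.75 * L,
    b = inBand & aAll < amin + 0.25 * L,
    c = inBand & aAll > amin + 0.75 * L,
    d = strip(1))
  if (withOuter) out$e <- strip(-1)
  idx <- (cc - 1L) * H + rr
  lapply(out, function(sel) idx[sel])
}

#' Partition the three areas into the 13 named regions
#'
#' Each area is Otsu-segmented (dark class); the largest component is taken as
#' the cell-body band. The band is split perpendicular to its local axis:
#' "a" is the central half along the axis, "b"/"c" the lateral quarters, and
#' the neuropil strips "d" (and "e" on the far side, DG only) run from just
#' beyond the band boundary to one band-width further out. Pixels are assigned
#' to at most one region (CA1, then CA3, then DG claim them in order).
#'
#' @param boxes output of \code{\link{selectAreas}}.
#' @param image the section image, [0, 255].
#' @param inward a point on the concave side of the bands (typically the
#'   centroid of the fitted control points); orients the neuropil strips.
#' @return a \code{\linkS4class{RegionSet}}, or a \code{segmentationFailure}
#'   (see \code{\link{segmentationFailed}}) when the band or a region is empty.
#' @export
partitionRegions <- function(boxes, image, inward) {
  assertGrayImage(image)
  ca1 <- partitionOneBox(boxes$CA1, image, inward, withOuter = FALSE)
  ca3 <- partitionOneBox(boxes$CA3, image, inward, withOuter = FALSE)
  dg <- partitionOneBox(boxes$DG, image, inward, withOuter = TRUE)
  if (is.null(ca1) || is.null(ca3) || is.null(dg))
    return(segFailure("empty band mask in at least one area"))
  regions <- c(setNames(ca1, paste0("CA1", names(ca1))),
               setNames(ca3, paste0("CA3", names(ca3))),
               setNames(dg, paste0("DG", names(dg))))
  regions <- regions[regionNamesCanonical()]
  taken <- integer(0)
  for (nm in names(regions)) {
    regions[[nm]] <- setdiff(regions[[nm]], taken)
    taken <- c(taken, regions[[nm]])
  }
  if (any(vapply(regions, length, integer(1)) == 0L))
    return(segFailure("empty region after partition"))
  newRegionSet(dim(image), regions,
               boxes = boxes[c("CA1", "CA3", "DG")],
               flags = if (nzchar(boxes$flag)) boxes$flag else character())
}

# local intensity features of pixels: raw value plus mean, SD and 16-bin
# histogram entropy of the 9 x 9 neighborhood
pixelFeatures <- function(image, pts, half = 4L) {
  H <- nrow(image); W <- ncol(image)
  t(apply(pts, 1L, function(p) {
    r <- clamp(p[1], 1, H); c <- clamp(p[2], 1, W)
    win <- image[max(1, r - half):min(H, r + half),
                 max(1, c - half):min(W, c + half)]
    hst <- tabulate(pmin(floor(win / 16), 15) + 1L, nbins = 16L)
    ph <- hst / sum(hst); ph <- ph[ph > 0]
    c(intensity = image[r, c], local_mean = mean(win), local_sd = sd(win),
      local_entropy = -sum(ph * log2(ph)))
  }))
}

#' Train the inside/outside pixel classifier
#'
#' Random forest distinguishing pixels inside the cell-body bands (stratum
#' pyramidale / granulosum) from pixels outside, trained on a synthetic cohort
#' with ground-truth band masks. 100 trees; deterministic under the seed.
#'
#' @param cohort output of \code{\link{generateCohort}}.
#' @param nPerImage training pixels sampled per section (half inside); 500
#'   keeps the classifier reliable on neuropil puncta, whose local texture
#'   resembles the band.
#' @param seed integer seed.
#' @return a \code{randomForest} classifier with levels "inside"/"outside".
#' @export
trainInsideForest <- function(cohort, nPerImage = 500L, seed = 1L) {
  rows <- withSeed(deriveSeed(seed, 71L), {
    lapply(cohort, function(sec) {
      band <- which(sec$truth$bandMask)
      outs <- which(!sec$truth$bandMask)
      n2 <- nPerImage %/% 2L
      pts <- arrayInd(c(sample(band, n2, replace = TRUE),
                        sample(outs, n2, replace = TRUE)),
                      dim(sec$image))
      cbind(as.data.frame(pixelFeatures(sec$image, pts)),
            y = rep(c("inside", "outside"), each = n2))
    })
  })
  df <- do.call(rbind, rows)
  withSeed(deriveSeed(seed, 72L),
           randomForest::randomForest(
             x = df[, 1:4], y = factor(df$y, c("inside", "outside")),
             ntree = 100L))
}

# QC feature row for one segmentation: accuracy of the 12-point test in the
# six probed regions plus region-statistics summaries
qcFeatureRow <- function(image, regions, rfInside, seed, nPoints = 12L) {
  probed <- c("CA1a", "CA1d", "CA3a", "CA3d", "DGa", "DGd")
  expected <- c(CA1a = "inside", CA1d = "outside", CA3a = "inside",
                CA3d = "outside", DGa = "inside", DGd = "outside")
  H <- regions@dim[1]
  hits <- withSeed(seed, {
    unlist(lapply(probed, function(nm) {
      pix <- regions@regions[[nm]]
      smp <- pix[sample.int(length(pix), nPoints, replace = TRUE)]
      pts <- cbind(((smp - 1L) %% H) + 1L, ((smp - 1L) %/% H) + 1L)
      pred <- predict(rfInside, as.data.frame(pixelFeatures(image, pts)))
      pred == expected[nm]
    }))
  })
  areas <- vapply(regions@regions, length, integer(1))
  sds <- vapply(regions@regions, function(ix) {
    v <- image[ix]
    if (length(v) > 1) sd(v) else 0
  }, numeric(1))
  data.frame(point_accuracy = mean(hits),
             log_mean_area = log(mean(areas)),
             log_min_area = log(max(min(areas), 1)),
             mean_intensity_sd = mean(sds))
}

# translate all masks of a RegionSet by (dr, dc), dropping pixels that leave
# the image — used to manufacture planted-failure training examples
shiftRegionSet <- function(rs, dr, dc) {
  H <- rs@dim[1]; W <- rs@dim[2]
  regions <- lapply(rs@regions, function(ix) {
    r <- ((ix - 1L) %% H) + 1L + dr
    c <- ((ix - 1L) %/% H) + 1L + dc
    ok <- r >= 1L & r <= H & c >= 1L & c <= W
    as.integer((c[ok] - 1L) * H + r[ok])
  })
  newRegionSet(c(H, W), regions, boxes = rs@boxes, flags = "shifted")
}

#' Train the segmentation accept/reject classifier
#'
#' Second-stage random forest: feature rows are (point accuracy, area and
#' intensity-SD summaries) from \code{\link{qcFeatureRow}}. Positive examples
#' come from ground-truth segmentations of the cohort; negatives from the same
#' segmentations shifted off the bands by three band-widths.
#'
#' @param cohort output of \code{\link{generateCohort}}.
#' @param rfInside classifier from \code{\link{trainInsideForest}}.
#' @param seed integer seed.
#' @return a \code{randomForest} classifier with levels "accept"/"reject".
#' @export
trainAcceptForest <- function(cohort, rfInside, seed = 1L) {
  rows <- lapply(seq_along(cohort), function(i) {
    sec <- cohort[[i]]
    bw <- sec$truth$params$band_width
    good <- qcFeatureRow(sec$image, sec$truth$regions, rfInside,
                         deriveSeed(seed, 500L + i))
    bad <- qcFeatureRow(sec$image,
                        shiftRegionSet(sec$truth$regions, round(3 * bw),
                                       round(3 * bw)),
                        rfInside, deriveSeed(seed, 600L + i))
    cbind(rbind(good, bad), y = c("accept", "reject"))
  })
  df <- do.call(rbind, rows)
  withSeed(deriveSeed(seed, 73L),
           randomForest::randomForest(
             x = df[, 1:4], y = factor(df$y, c("accept", "reject")),
             ntree = 100L))
}

#' Quality-control a segmentation
#'
#' Samples 12 random points in each of CA1a, CA1d, CA3a, CA3d, DGa and DGd,
#' classifies them with the inside/outside forest, and feeds the resulting
#' accuracy plus region statistics (areas, intensity SDs) to the accept/reject
#' forest. Deterministic given the seed.
#'
#' @param image section image, [0, 255].
#' @param regions a \code{\linkS4class{RegionSet}}.
#' @param rfInside,rfAccept trained forests (see
#'   \code{\link{trainInsideForest}}, \code{\link{trainAcceptForest}}).
#' @param seed integer seed for the point sampling.
#' @return \code{list(point_accuracy, region_stats, accepted, n_points)}.
#' @export
qcSegmentation <- function(image, regions, rfInside, rfAccept, seed = 1L) {
  if (is.null(rfInside) || is.null(rfAccept))
    stop("both forests must be trained before QC")
  row <- qcFeatureRow(image, regions, rfInside, seed)
  accepted <- predict(rfAccept, row) == "accept"
  list(point_accuracy = row$point_accuracy,
       region_stats = data.frame(
         region = names(regions@regions),
         area = vapply(regions@regions, length, integer(1)),
         intensity_sd = vapply(regions@regions, function(ix)
           if (length(ix) > 1) sd(image[ix]) else 0, numeric(1)),
         row.names = NULL),
       accepted = unname(accepted),
       n_points = 72L)
}

#' Process a slice series with retry and discard logic
#'
#' Attempts the default atlas level 145 first, then alternates outward toward
#' the range boundaries (144, 146, 143, 147, ...) over the levels present in
#' the series. Each attempt runs preprocessing, shape fitting, area selection,
#' partition and QC; the first accepted segmentation wins. When every slice
#' fails the gene is discarded.
#'
#' @param series list of \code{list(image, level)} with levels in [117, 175].
#' @param model a \code{\linkS4class{ShapeModel}}.
#' @param rfInside,rfAccept trained QC forests.
#' @param de \code{\link{deParams}} for shape fitting.
#' @param seed integer seed.
#' @param defaultLevel preferred atlas level (default 145).
#' @return on success \code{list(discarded = FALSE, regions, atlas_level,
#'   loc, qc, attempts)}; otherwise \code{list(discarded = TRUE, reason,
#'   attempts)}.
#' @export
processSeries <- function(series, model, rfInside, rfAccept,
                          de = deParams(), seed = 1L, defaultLevel = 145L) {
  if (length(series) == 0L)
    return(list(discarded = TRUE, reason = "empty series", attempts = 0L))
  levels <- vapply(series, function(s) as.integer(s$level), integer(1))
  if (any(levels < 117L | levels > 175L))
    stop("series levels must lie in [117, 175]")
  offs <- c(0L, as.vector(rbind(-seq_len(58L), seq_len(58L))))
  order_ <- unique(defaultLevel + offs)
  order_ <- order_[order_ %in% levels]
  attempts <- 0L
  for (lv in order_) {
    attempts <- attempts + 1L
    sec <- series[[match(lv, levels)]]
    pre <- preprocessRoi(sec$image)
    if (!any(pre$mask)) next
    deLv <- de
    deLv$seed <- deriveSeed(seed, 10L * lv + 1L)
    loc <- fitShape(sec$image, model, de = deLv, pre = pre)
    if (!loc@success) next
    boxes <- selectAreas(loc)
    regions <- partitionRegions(boxes, sec$image,
                                inward = colMeans(controlPoints(loc)))
    if (segmentationFailed(regions)) next
    qc <- qcSegmentation(sec$image, regions, rfInside, rfAccept,
                         seed = deriveSeed(seed, 10L * lv + 2L))
    if (qc$accepted) {
      loc@atlasLevel <- lv
      return(list(discarded = FALSE, regions = regions, atlas_level = lv,
                  loc = loc, qc = qc, attempts = attempts))
    }
  }
  list(discarded = TRUE, reason = "all slices rejected by QC",
       attempts = attempts)
}
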