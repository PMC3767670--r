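#' @include AllClasses.R optim.R preprocess.R
NULL

#' Build the deformable shape model from training shapes
#'
#' Point-distribution model in the Active Shape Model tradition: training
#' shapes (8 AH + 7 DG landmarks each) are centered on their centroid and the
#' principal components of the stacked coordinates become the deformation
#' modes. Mode coefficients are bounded at \code{modeBoundSd} standard
#' deviations, so sampled shapes stay inside the training variation.
#'
#' @param shapes list of 15 x 2 (row, col) landmark matrices.
#' @param varFrac fraction of variance the retained modes must explain.
#' @param maxModes cap on the number of modes.
#' @param modeBoundSd coefficient bound in SD units (default 3).
#' @return a \code{\linkS4class{ShapeModel}}.
#' @export
buildShapeModel <- function(shapes, varFrac = 0.95, maxModes = 6L,
                            modeBoundSd = 3) {
  stopifnot(length(shapes) >= 1L)
  flat <- t(vapply(shapes, function(s) {
    stopifnot(all(dim(s) == c(15L, 2L)))
    s <- sweep(s, 2, colMeans(s))
    as.numeric(s)
  }, numeric(30L)))
  mean30 <- colMeans(flat)
  modes <- matrix(numeric(0), 30L, 0L)
  sdev <- numeric(0)
  if (nrow(flat) > 1L) {
    pc <- prcomp(flat, center = TRUE)
    keep <- which(pc$sdev > 1e-8)
    if (length(keep)) {
      cum <- cumsum(pc$sdev[keep]^2) / sum(pc$sdev[keep]^2)
      k <- min(max(which(cum >= varFrac)[1], 1L), maxModes, length(keep))
      modes <- pc$rotation[, seq_len(k), drop = FALSE]
      sdev <- pc$sdev[seq_len(k)]
    }
  }
  mean15 <- matrix(mean30, 15L, 2L)
  new("ShapeModel", meanShape = mean15, modes = modes, sdev = sdev,
      modeBoundSd = modeBoundSd,
      refScale = sqrt(mean(rowSums(mean15^2))))
}

#' Instantiate a shape from pose and mode coefficients
#'
#' @param model a \code{\linkS4class{ShapeModel}}.
#' @param pose c(row, col, rotation, scale): centroid position, rotation in
#'   radians, isotropic scale.
#' @param b mode coefficients (length = number of modes).
#' @return 15 x 2 matrix of (row, col) points (8 AH then 7 DG).
#' @export
shapeFromParams <- function(model, pose, b = numeric(0)) {
  pts <- model@meanShape
  if (length(b)) {
    stopifnot(length(b) == ncol(model@modes))
    pts <- pts + matrix(model@modes %*% b, 15L, 2L)
  }
  th <- pose[3]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  pts <- pose[4] * pts %*% t(R)
  cbind(pts[, 1] + pose[1], pts[, 2] + pose[2])
}

# resample a polyline at n evenly spaced arc-length positions
samplePolyline <- function(pts, n) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cl <- c(0, cumsum(seg))
  L <- cl[length(cl)]
  if (L == 0) return(pts[rep(1L, n), , drop = FALSE])
  s <- seq(0, L, length.out = n)
  r <- approx(cl, pts[, 1], xout = s, ties = "ordered")$y
  c2 <- approx(cl, pts[, 2], xout = s, ties = "ordered")$y
  cbind(r, c2)
}

# fixed interpolation weights placing k evenly spaced samples on each segment
# of an nPts-point polyline (plus the final endpoint); sampling then reduces
# to W %*% pts, which keeps the DE objective cheap
polylineWeights <- local({
  cache <- list()
  function(nPts, k) {
    key <- paste(nPts, k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    nSeg <- nPts - 1L
    W <- matrix(0, nSeg * k + 1L, nPts)
    row <- 1L
    for (j in seq_len(nSeg)) {
      for (t in (seq_len(k) - 1L) / k) {
        W[row, j] <- 1 - t
        W[row, j + 1L] <- t
        row <- row + 1L
      }
    }
    W[row, nPts] <- 1
    cache[[key]] <<- W
    W
  }
})

#' Energy of a candidate AH/DG placement
#'
#' Lower is better. The polylines through the candidate control points are
#' sampled at a fixed number of evenly spaced steps per segment (six, so
#' samples are approximately equidistant in arc length for near-equidistant
#' control points); the energy is minus the mean inverted intensity along the
#' samples (dark cell-body bands attract) minus \code{lambda} times the
#' fraction of samples falling inside the binary foreground mask. Samples
#' outside the image contribute the worst value of both terms.
#'
#' @param image enhanced intensity image, [0, 255].
#' @param mask binary foreground mask from \code{\link{preprocessRoi}}.
#' @param ahPoints 8 x 2 candidate AH points; \code{dgPoints} 7 x 2.
#' @param dgPoints 7 x 2 candidate DG points.
#' @param lambda weight of the foreground-overlap term (default 1).
#' @param stepsPerSegment samples per polyline segment (default 6).
#' @return scalar energy.
#' @export
shapeEnergy <- function(image, mask, ahPoints, dgPoints, lambda = 1,
                        stepsPerSegment = 6L) {
  s <- rbind(polylineWeights(nrow(ahPoints), stepsPerSegment) %*% ahPoints,
             polylineWeights(nrow(dgPoints), stepsPerSegment) %*% dgPoints)
  H <- nrow(image); W <- ncol(image)
  ri <- round(s[, 1]); ci <- round(s[, 2])
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  ints <- rep(255, nrow(s))
  fg <- rep(0, nrow(s))
  if (any(ok)) {
    ii <- (ci[ok] - 1) * H + ri[ok]
    ints[ok] <- image[ii]
    fg[ok] <- mask[ii]
  }
  -mean((255 - ints) / 255) - lambda * mean(fg)
}

#' Fit the shape model to an image with Differential Evolution
#'
#' Optimizes pose (translation, rotation, isotropic scale) plus bounded mode
#' coefficients against \code{\link{shapeEnergy}} computed on the preprocessed
#' image and foreground mask. Fails cleanly (success = FALSE) when the
#' foreground mask is empty, e.g. on a blank section.
#'
#' @param image raw section image, [0, 255].
#' @param model a \code{\linkS4class{ShapeModel}}.
#' @param de \code{\link{deParams}}; the seed inside governs the fit.
#' @param pre optional precomputed \code{\link{preprocessRoi}} output (saves
#'   recomputation when the caller already has it).
#' @param ref_stats optional training-ROI statistics for normalization.
#' @param lambda energy weight, see \code{\link{shapeEnergy}}.
#' @param rotBound,scaleBounds pose bounds (radians; c(min, max) scale).
#' @param init optional initial parameter vector (pose then coefficients)
#'   seeded into the DE population.
#' @return a \code{\linkS4class{LocalizationResult}}.
#' @export
fitShape <- function(image, model, de = deParams(), pre = NULL,
                     ref_stats = NULL, lambda = 1, rotBound = 0.3,
                     scaleBounds = c(0.75, 1.3), init = NULL) {
  if (is.null(pre)) pre <- preprocessRoi(image, ref_stats)
  if (!any(pre$mask))
    return(new("LocalizationResult",
               ahPoints = matrix(numeric(0), 0, 2),
               dgPoints = matrix(numeric(0), 0, 2),
               energy = NA_real_, roi = numeric(0), success = FALSE))
  idx <- which(pre$mask, arr.ind = TRUE)
  roi <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
  k <- ncol(model@modes)
  lower <- c(roi[1], roi[3], -rotBound, scaleBounds[1],
             if (k) -model@modeBoundSd * model@sdev)
  upper <- c(roi[2], roi[4], rotBound, scaleBounds[2],
             if (k) model@modeBoundSd * model@sdev)
  obj <- function(theta) {
    pts <- shapeFromParams(model, theta[1:4],
                           if (k) theta[4 + seq_len(k)] else numeric(0))
    shapeEnergy(pre$image, pre$mask, pts[1:8, , drop = FALSE],
                pts[9:15, , drop = FALSE], lambda = lambda)
  }
  fit <- deOptimize(obj, lower, upper, de,
                    init = if (is.null(init)) NULL else matrix(init, 1L))
  pts <- shapeFromParams(model, fit$par[1:4],
                         if (k) fit$par[4 + seq_len(k)] else numeric(0))
  new("LocalizationResult",
      ahPoints = pts[1:8, , drop = FALSE],
      dgPoints = pts[9:15, , drop = FALSE],
      energy = fit$value, roi = as.numeric(roi), success = TRUE)
}

# affine warp of target coordinates: x' = A (x - ctr) + ctr + t, with
# par = c(a11, a12, a21, a22, t_row, t_col)
affineApply <- function(par, pts, ctr) {
  A <- matrix(par[1:4], 2L, 2L, byrow = TRUE)
  sw <- sweep(pts, 2, ctr)
  sweep(sw %*% t(A), 2, ctr + par[5:6], "+")
}

nccScore <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Register a section to a reference atlas (two-step affine)
#'
#' Step 1 refines a 6-parameter affine transform per atlas slice with a
#' damped least-squares (Levenberg-Marquardt) fit of the intensity residuals
#' on a subsampled grid; step 2 refines the best candidate slices with
#' \code{\link{psoOptimize}} on normalized cross-correlation. Both images are
#' lightly smoothed first to widen the attraction basin. Returns the
#' best-matching atlas level and the slice's hippocampus ROI mapped through
#' the fitted transform.
#'
#' @param image target section, matrix in [0, 255].
#' @param atlas list of \code{list(level, image, roi)} with roi =
#'   c(row0, row1, col0, col1) on the atlas slice.
#' @param pso \code{\link{psoParams}} for the refinement step.
#' @param gridStep grid subsampling step in pixels (default 3).
#' @param refineTop number of step-1 candidates refined by PSO (default 2).
#' @param minNcc similarity floor; below it registration is declared failed
#'   (pipeline then retries another slice).
#' @param blurSigma Gaussian smoothing sigma (default 2).
#' @return \code{list(level, roi, transform, ncc, failed)}; on failure
#'   \code{level} is NA and \code{failed} is TRUE. \code{transform[5:6]} is
#'   the recovered translation (row, col).
#' @export
registerToAtlas <- function(image, atlas, pso = psoParams(), gridStep = 3L,
                            refineTop = 2L, minNcc = 0.5, blurSigma = 2) {
  if (length(atlas) == 0L) stop("atlas must be nonempty")
  blur <- function(m)
    matrix(as.numeric(EBImage::imageData(
      EBImage::gblur(EBImage::Image(m / 255), sigma = blurSigma))),
      nrow(m), ncol(m)) * 255
  tgt <- blur(image)
  ctr <- c((nrow(tgt) + 1) / 2, (ncol(tgt) + 1) / 2)

  step1 <- lapply(atlas, function(sl) {
    ref <- blur(sl$image)
    margin <- 4L
    gr <- seq(1L + margin, nrow(ref) - margin, by = gridStep)
    gc <- seq(1L + margin, ncol(ref) - margin, by = gridStep)
    grid <- cbind(rep(gr, times = length(gc)), rep(gc, each = length(gr)))
    refv <- ref[grid]
    resid <- function(par) {
      w <- affineApply(par, grid, ctr)
      bilinearSample(tgt, w[, 1], w[, 2], fill = mean(refv)) - refv
    }
    # hitting maxiter is fine here: step 2 (PSO) refines the fit anyway
    lm <- suppressWarnings(
      minpack.lm::nls.lm(par = c(1, 0, 0, 1, 0, 0), fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 30, ptol = 1e-6)))
    par <- lm$par
    w <- affineApply(par, grid, ctr)
    ncc <- nccScore(bilinearSample(tgt, w[, 1], w[, 2], fill = mean(refv)),
                    refv)
    list(slice = sl, par = par, ncc = ncc, grid = grid, refv = refv)
  })

  ord <- order(-vapply(step1, `[[`, numeric(1), "ncc"))
  cand <- step1[ord[seq_len(min(refineTop, length(step1)))]]
  refined <- lapply(seq_along(cand), function(i) {
    cd <- cand[[i]]
    obj <- function(par) {
      w <- affineApply(par, cd$grid, ctr)
      -nccScore(bilinearSample(tgt, w[, 1], w[, 2], fill = mean(cd$refv)),
                cd$refv)
    }
    lower <- cd$par - c(rep(0.12, 4), 12, 12)
    upper <- cd$par + c(rep(0.12, 4), 12, 12)
    ps <- pso
    ps$seed <- deriveSeed(pso$seed, i)
    fit <- psoOptimize(obj, lower, upper, ps, init = matrix(cd$par, 1L))
    list(slice = cd$slice, par = fit$par, ncc = -fit$value)
  })
  best <- refined[[which.max(vapply(refined, `[[`, numeric(1), "ncc"))]]
  if (best$ncc < minNcc)
    return(list(level = NA_integer_, roi = NULL, transform = best$par,
                ncc = best$ncc, failed = TRUE))
  rb <- best$slice$roi
  corners <- cbind(c(rb[1], rb[1], rb[2], rb[2]),
                   c(rb[3], rb[4], rb[3], rb[4]))
  wc <- affineApply(best$par, corners, ctr)
  roi <- c(clamp(floor(min(wc[, 1])), 1, nrow(image)),
           clamp(ceiling(max(wc[, 1])), 1, nrow(image)),
           clamp(floor(min(wc[, 2])), 1, ncol(image)),
           clamp(ceiling(max(wc[, 2])), 1, ncol(image)))
  list(level = as.integer(best$slice$level), roi = roi, transform = best$par,
       ncc = best$ncc, failed = FALSE)
}
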