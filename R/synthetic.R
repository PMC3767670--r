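#' @include AllClasses.R utils.R
NULL

#' Parameters of a synthetic ISH section
#'
#' Describes one simulated parasagittal hippocampal section: two
#' non-intersecting parametric arcs (the Ammon's-horn pyramidal band and the
#' dentate-gyrus granular band), dark punctate ISH signal dense inside the
#' cell-body bands, and a controllable fraction of puncta spilling into the
#' flanking neuropil margin on the stratum-radiatum side of each band.
#'
#' The neuropil margin is a strip of width \code{2 * band_width} starting
#' \code{ceiling(puncta_radius) + 1} px beyond the band edge (the thin guard
#' gap keeps band and neuropil signal optically separate, so a section with
#' zero enrichment has a margin of exactly \code{background_level} before
#' noise). \code{neuropil_enrichment} (e) is the ratio of neuropil to band
#' puncta density; e = 0 plants no neuropil signal.
#'
#' @param image_size c(height, width) in pixels.
#' @param ah_curve,dg_curve arcs as \code{list(center = c(row, col),
#'   radii = c(r_row, r_col), span = c(theta0, theta1))}; points follow
#'   \code{center + (r_row sin t, r_col cos t)}.
#' @param band_width full width of the cell-body bands, pixels.
#' @param soma_density puncta per 100 px^2 inside the bands (> 0).
#' @param neuropil_enrichment e >= 0, neuropil / band puncta density ratio.
#' @param puncta_radius punctum radius, pixels; rendered with a Gaussian
#'   falloff (sigma = radius / 2) truncated at the radius.
#' @param band_contrast solid darkening of band pixels beneath the puncta
#'   (cell-body layers are near-uniformly dark in colorimetric ISH).
#' @param puncta_amplitude peak darkening of a single punctum.
#' @param background_level background intensity in [0, 255].
#' @param noise_sd Gaussian pixel noise SD (intensity units).
#' @param seed integer seed; the whole section is reproducible from it.
#' @return a validated parameter list of class \code{SectionParams}.
#' @export
sectionParams <- function(image_size = c(200L, 280L),
                          ah_curve = list(center = c(105, 145),
                                          radii = c(66, 88),
                                          span = c(-0.12 * pi, 0.92 * pi)),
                          dg_curve = list(center = c(100, 143),
                                          radii = c(28, 44),
                                          span = c(-0.05 * pi, 0.85 * pi)),
                          band_width = 6,
                          soma_density = 8,
                          neuropil_enrichment = 0,
                          puncta_radius = 1.6,
                          band_contrast = 90,
                          puncta_amplitude = 140,
                          background_level = 220,
                          noise_sd = 6,
                          seed = 1L) {
  p <- list(image_size = as.integer(image_size), ah_curve = ah_curve,
            dg_curve = dg_curve, band_width = band_width,
            soma_density = soma_density,
            neuropil_enrichment = neuropil_enrichment,
            puncta_radius = puncta_radius, band_contrast = band_contrast,
            puncta_amplitude = puncta_amplitude,
            background_level = background_level, noise_sd = noise_sd,
            seed = as.integer(seed))
  class(p) <- "SectionParams"
  validateSectionParams(p)
  p
}

validateSectionParams <- function(p) {
  stopifnot(length(p$image_size) == 2L, all(p$image_size >= 32L))
  if (p$soma_density <= 0) stop("soma_density must be > 0")
  if (p$neuropil_enrichment < 0) stop("neuropil_enrichment must be >= 0")
  if (p$band_width <= 0 || p$puncta_radius <= 0)
    stop("band_width and puncta_radius must be > 0")
  if (p$background_level < 0 || p$background_level > 255)
    stop("background_level must lie in [0, 255]")
  reach <- p$band_width / 2 + ceiling(p$puncta_radius)
  for (cv in list(p$ah_curve, p$dg_curve)) {
    pts <- curvePoints(cv, 200L)
    if (min(pts[, 1]) - reach < 1 || max(pts[, 1]) + reach > p$image_size[1] ||
        min(pts[, 2]) - reach < 1 || max(pts[, 2]) + reach > p$image_size[2])
      stop("curve (plus band) does not fit inside the image")
  }
  a <- curvePoints(p$ah_curve, 200L); d <- curvePoints(p$dg_curve, 200L)
  gap <- sqrt(min(outer(a[, 1], d[, 1], "-")^2 + outer(a[, 2], d[, 2], "-")^2))
  if (gap <= p$band_width + 2)
    stop("ah_curve and dg_curve intersect or run too close")
  invisible(p)
}

# points along a parametric elliptical arc: rows = (row, col)
curvePoints <- function(curve, n) {
  th <- seq(curve$span[1], curve$span[2], length.out = n)
  cbind(curve$center[1] + curve$radii[1] * sin(th),
        curve$center[2] + curve$radii[2] * cos(th))
}

# Per-pixel geometry relative to an arc: distance to the midline, arc
# coordinate t in [0,1] of the nearest midline sample, and which side of the
# curve the pixel lies on (inner = toward the arc center).
arcGeometry <- function(curve, dim, nsamp = 240L) {
  H <- dim[1]; W <- dim[2]
  pts <- curvePoints(curve, nsamp)
  yy <- rep(seq_len(H), times = W)
  xx <- rep(seq_len(W), each = H)
  best <- rep(Inf, H * W)
  arg <- rep(1L, H * W)
  for (k in seq_len(nsamp)) {
    d2 <- (yy - pts[k, 1])^2 + (xx - pts[k, 2])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    arg[upd] <- k
  }
  u <- sqrt(((yy - curve$center[1]) / curve$radii[1])^2 +
            ((xx - curve$center[2]) / curve$radii[2])^2)
  list(dist = matrix(sqrt(best), H, W),
       tcoord = matrix((arg - 1) / (nsamp - 1), H, W),
       inner = matrix(u < 1, H, W))
}

# Split one arc's band/margin into named sub-regions over a t-sub-span.
# kinds: a = central half of the band along the arc, b/c = lateral quarters,
# d = inner neuropil strip, e = outer neuropil strip (DG only).
arcSubRegions <- function(geom, span, band_hw, marg0, marg1, withOuter) {
  s <- (geom$tcoord - span[1]) / (span[2] - span[1])
  inSpan <- s >= 0 & s <= 1
  band <- geom$dist <= band_hw & inSpan
  marg <- geom$dist > marg0 & geom$dist <= marg1 & inSpan
  out <- list(a = band & s >= 0.25 & s <= 0.75,
              b = band & s < 0.25,
              c = band & s > 0.75,
              d = marg & geom$inner)
  if (withOuter) out$e <- marg & !geom$inner
  out
}

#' Generate one synthetic ISH section with ground truth
#'
#' Renders dark circular puncta (Poisson point process) at density
#' \code{soma_density} per 100 px^2 inside the cell-body bands and at density
#' \code{e * soma_density} inside the flanking neuropil margins, on a light
#' noisy background. Bands additionally carry a solid base darkening
#' (\code{band_contrast}) beneath the puncta. Bit-identical output for a fixed
#' seed; for fixed seed and geometry, raising e only adds neuropil puncta
#' (coupled counts), so the margin can only get darker.
#'
#' @param params a \code{\link{sectionParams}} object.
#' @return \code{list(image, truth)}: \code{image} is an integer matrix in
#'   [0, 255]; \code{truth} is a list with \code{ahPoints} (8 x 2),
#'   \code{dgPoints} (7 x 2), \code{regions} (a \code{\link{RegionSet}} of the
#'   13 true masks), \code{bandMask}/\code{neuropilMask} (full-span logical
#'   matrices), \code{puncta} (data frame of planted centers with compartment
#'   labels), \code{enrichment} and \code{params}.
#' @export
generateSection <- function(params) {
  validateSectionParams(params)
  H <- params$image_size[1]; W <- params$image_size[2]
  bw <- params$band_width; rp <- params$puncta_radius
  gap <- ceiling(rp) + 1
  marg0 <- bw / 2 + gap
  marg1 <- marg0 + 2 * bw

  gAH <- arcGeometry(params$ah_curve, c(H, W))
  gDG <- arcGeometry(params$dg_curve, c(H, W))

  bandAH <- gAH$dist <= bw / 2
  bandDG <- gDG$dist <= bw / 2
  margAH <- gAH$dist > marg0 & gAH$dist <= marg1 & gAH$inner
  margDG <- gDG$dist > marg0 & gDG$dist <= marg1 & gDG$inner
  # a pixel can only be claimed by one structure (guaranteed apart by validity)
  margAH <- margAH & !bandDG & !margDG

  lam <- params$soma_density / 100
  e <- params$neuropil_enrichment

  sampleCenters <- function(mask, n, seed) {
    pix <- which(mask)
    if (n == 0L || length(pix) == 0L)
      return(cbind(numeric(0), numeric(0)))
    withSeed(seed, {
      us <- runif(3L * n)
      idx <- pix[pmin(floor(us[seq(1L, 3L * n, by = 3L)] * length(pix)) + 1L,
                      length(pix))]
      r <- ((idx - 1L) %% H) + 1L + us[seq(2L, 3L * n, by = 3L)] - 0.5
      c <- ((idx - 1L) %/% H) + 1L + us[seq(3L, 3L * n, by = 3L)] - 0.5
      cbind(r, c)
    })
  }

  nBandAH <- withSeed(deriveSeed(params$seed, 11L), rpois(1L, lam * sum(bandAH)))
  nBandDG <- withSeed(deriveSeed(params$seed, 12L), rpois(1L, lam * sum(bandDG)))
  # coupled margin counts: qpois of a fixed uniform is non-decreasing in e
  uM <- withSeed(deriveSeed(params$seed, 13L), runif(2L))
  nMargAH <- qpois(uM[1], e * lam * sum(margAH))
  nMargDG <- qpois(uM[2], e * lam * sum(margDG))

  centers <- rbind(sampleCenters(bandAH, nBandAH, deriveSeed(params$seed, 21L)),
                   sampleCenters(bandDG, nBandDG, deriveSeed(params$seed, 22L)),
                   sampleCenters(margAH, nMargAH, deriveSeed(params$seed, 23L)),
                   sampleCenters(margDG, nMargDG, deriveSeed(params$seed, 24L)))
  compartment <- rep(c("band_AH", "band_DG", "neuropil_AH", "neuropil_DG"),
                     c(nBandAH, nBandDG, nMargAH, nMargDG))

  img <- matrix(params$background_level, H, W)
  img[bandAH | bandDG] <- img[bandAH | bandDG] - params$band_contrast

  hw <- ceiling(rp)
  sig2 <- (rp / 2)^2
  if (nrow(centers)) {
    for (i in seq_len(nrow(centers))) {
      r0 <- max(1L, floor(centers[i, 1] - hw))
      r1 <- min(H, ceiling(centers[i, 1] + hw))
      c0 <- max(1L, floor(centers[i, 2] - hw))
      c1 <- min(W, ceiling(centers[i, 2] + hw))
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
      dip <- params$puncta_amplitude * exp(-d2 / (2 * sig2))
      dip[d2 > rp^2] <- 0
      img[rr, cc] <- img[rr, cc] - dip
    }
  }

  if (params$noise_sd > 0)
    img <- img + withSeed(deriveSeed(params$seed, 31L),
                          matrix(rnorm(H * W, 0, params$noise_sd), H, W))
  img <- matrix(as.integer(round(clamp(img, 0, 255))), H, W)

  ahPts <- curvePoints(params$ah_curve, 8L)
  dgPts <- curvePoints(params$dg_curve, 7L)

  subAH <- arcSubRegions(gAH, c(0, 1), bw / 2, marg0, marg1, withOuter = FALSE)
  ca1 <- arcSubRegions(gAH, c(0, 0.45), bw / 2, marg0, marg1, withOuter = FALSE)
  ca3 <- arcSubRegions(gAH, c(0.55, 1), bw / 2, marg0, marg1, withOuter = FALSE)
  dg <- arcSubRegions(gDG, c(0, 1), bw / 2, marg0, marg1, withOuter = TRUE)
  # keep the AH/DG structures from claiming each other's pixels
  notDG <- !(bandDG | margDG | dg$e)
  masks <- list(
    CA1a = ca1$a & notDG, CA1b = ca1$b & notDG, CA1c = ca1$c & notDG,
    CA1d = ca1$d & notDG,
    CA3a = ca3$a & notDG, CA3b = ca3$b & notDG, CA3c = ca3$c & notDG,
    CA3d = ca3$d & notDG,
    DGa = dg$a, DGb = dg$b, DGc = dg$c, DGd = dg$d,
    DGe = dg$e & !(bandAH | margAH))
  regions <- newRegionSet(c(H, W), lapply(masks, which))

  truth <- list(
    ahPoints = ahPts, dgPoints = dgPts, regions = regions,
    bandMask = bandAH | bandDG,
    neuropilMask = margAH | margDG,
    puncta = data.frame(row = centers[, 1], col = centers[, 2],
                        compartment = compartment,
                        stringsAsFactors = FALSE),
    enrichment = e, params = params)
  class(truth) <- c("GroundTruth", "list")
  list(image = img, truth = truth)
}

# jitter the section geometry so cohort shapes vary (drawn from the current
# RNG stream; callers wrap in withSeed)
jitterGeometry <- function(params, center_sd = 3, radius_frac = 0.05,
                           span_shift = 0.04) {
  jc <- function(cv) {
    cv$center <- cv$center + rnorm(2, 0, center_sd)
    cv$radii <- cv$radii * runif(2, 1 - radius_frac, 1 + radius_frac)
    cv$span <- cv$span + runif(1, -span_shift, span_shift) * pi
    cv
  }
  params$ah_curve <- jc(params$ah_curve)
  params$dg_curve <- jc(params$dg_curve)
  params
}

#' Generate a labeled cohort of synthetic sections
#'
#' Produces \code{n_pos} positive sections with neuropil enrichment drawn
#' uniformly from \code{e_pos} and \code{n_neg} negatives from \code{e_neg}
#' (the ranges must be disjoint with positives above negatives). Geometry is
#' jittered per section so shapes vary as real sections do. The default
#' 3 positives / 17 negatives mirrors the 20-gene training design used to
#' train the screen.
#'
#' @param n_pos,n_neg cohort sizes.
#' @param e_pos,e_neg c(min, max) enrichment ranges; \code{min(e_pos) >
#'   max(e_neg)} is required.
#' @param seed master seed.
#' @param base_params template \code{\link{sectionParams}}.
#' @param jitter jitter geometry per section (default TRUE).
#' @return list of \code{list(id, image, truth, label)} with labels
#'   "positive"/"negative".
#' @export
generateCohort <- function(n_pos = 3L, n_neg = 17L,
                           e_pos = c(1.2, 1.6), e_neg = c(0, 0.3),
                           seed = 1L, base_params = sectionParams(),
                           jitter = TRUE) {
  if (n_pos > 0 && n_neg > 0 && min(e_pos) <= max(e_neg))
    stop("enrichment ranges must be disjoint with e_pos above e_neg")
  mk <- function(i, id, label, erange) {
    p <- base_params
    p$seed <- deriveSeed(seed, 2000L + i)
    p <- withSeed(deriveSeed(seed, 1000L + i), {
      p$neuropil_enrichment <- runif(1, erange[1], erange[2])
      if (jitter) p <- jitterGeometry(p)
      p
    })
    sec <- generateSection(p)
    list(id = id, image = sec$image, truth = sec$truth, label = label)
  }
  out <- vector("list", n_pos + n_neg)
  i <- 0L
  for (k in seq_len(n_pos)) {
    i <- i + 1L
    out[[i]] <- mk(i, sprintf("pos%02d", k), "positive", e_pos)
  }
  for (k in seq_len(n_neg)) {
    i <- i + 1L
    out[[i]] <- mk(i, sprintf("neg%02d", k), "negative", e_neg)
  }
  out
}

#' Generate a graded synthetic screen
#'
#' A screen of \code{n} sections whose planted neuropil enrichment is evenly
#' spaced over \code{e_range}, used to test rank recovery against the planted
#' ordering.
#'
#' @param n number of sections.
#' @param e_range c(min, max) enrichment span (default 0 to 2).
#' @param seed master seed.
#' @param base_params template \code{\link{sectionParams}}.
#' @param jitter jitter geometry per section.
#' @return list of \code{list(id, image, truth, enrichment)}.
#' @export
generateScreen <- function(n = 30L, e_range = c(0, 2), seed = 1L,
                           base_params = sectionParams(), jitter = TRUE) {
  es <- seq(e_range[1], e_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    p <- base_params
    p$seed <- deriveSeed(seed, 4000L + i)
    p$neuropil_enrichment <- es[i]
    if (jitter)
      p <- withSeed(deriveSeed(seed, 3000L + i), jitterGeometry(p))
    sec <- generateSection(p)
    list(id = sprintf("gene%03d", i), image = sec$image, truth = sec$truth,
         enrichment = es[i])
  })
}

#' Write a section (PNG + ground-truth sidecar)
#'
#' @param image integer matrix in [0, 255].
#' @param truth ground truth from \code{\link{generateSection}} (or NULL).
#' @param path output PNG path; the sidecar gets extension ".truth.tsv".
#' @param label optional label recorded in the sidecar.
#' @return invisibly, the PNG path.
#' @export
writeSection <- function(image, truth = NULL, path, label = NA_character_) {
  assertGrayImage(image)
  png::writePNG(image / 255, target = path)
  if (!is.null(truth)) {
    fmtPts <- function(p)
      paste(sprintf("%.3f,%.3f", p[, 1], p[, 2]), collapse = ";")
    lines <- c(paste0("label\t", label),
               paste0("enrichment\t", format(truth$enrichment, digits = 10)),
               paste0("ah_points\t", fmtPts(truth$ahPoints)),
               paste0("dg_points\t", fmtPts(truth$dgPoints)))
    writeLines(lines, sub("\\.png$", ".truth.tsv", path))
  }
  invisible(path)
}

#' Read an 8-bit grayscale PNG as an integer matrix in [0, 255]
#'
#' @param path PNG path.
#' @return integer matrix.
#' @export
readSectionPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Write a cohort to disk
#'
#' Writes one PNG plus ground-truth sidecar per section and a TSV manifest
#' (id, path, label, enrichment).
#'
#' @param cohort output of \code{\link{generateCohort}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    p <- file.path(dir, paste0(s$id, ".png"))
    writeSection(s$image, s$truth, p,
                 label = if (!is.null(s$label)) s$label else NA_character_)
    data.frame(id = s$id, path = p,
               label = if (!is.null(s$label)) s$label else NA_character_,
               enrichment = s$truth$enrichment, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
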