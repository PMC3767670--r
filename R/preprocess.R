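#' @include utils.R
NULL

#' Otsu threshold of an 8-bit image
#'
#' Computes the threshold T maximizing the between-class variance of the
#' integer histogram; pixels with intensity <= T form the dark class. Uses the
#' cumulative-histogram recurrence (the test suite checks it against an
#' exhaustive 256-threshold search on raw pixels).
#'
#' @param image matrix with values in [0, 255].
#' @return integer threshold in [0, 254], or NA for a constant image.
#' @export
otsuThreshold <- function(image) {
  assertGrayImage(image)
  v <- as.integer(round(image))
  if (min(v) == max(v)) return(NA_integer_)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  muT <- mu[256]
  w0 <- omega[1:255]
  sb <- (muT * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  as.integer(which.max(sb) - 1L)
}

#' Otsu segmentation with dark-class foreground
#'
#' ISH signal is dark on a light background, so the foreground is the class at
#' or below the Otsu threshold.
#'
#' @param area matrix with values in [0, 255] and at least two distinct
#'   intensities.
#' @return logical mask with attributes \code{threshold} (the Otsu threshold)
#'   and \code{flag} ("" or "constant"); a constant input yields an all-FALSE
#'   mask flagged "constant".
#' @export
otsuSegment <- function(area) {
  thr <- otsuThreshold(area)
  if (is.na(thr)) {
    m <- matrix(FALSE, nrow(area), ncol(area))
    attr(m, "threshold") <- NA_integer_
    attr(m, "flag") <- "constant"
    return(m)
  }
  m <- matrix(round(area) <= thr, nrow(area), ncol(area))
  attr(m, "threshold") <- thr
  attr(m, "flag") <- ""
  m
}

#' Keep the k largest connected components of a binary mask
#'
#' Components are 8-connected; size ties are broken by raster order of the
#' component's first pixel (lower top-left wins), which is the labeling order
#' of \code{EBImage::bwlabel}.
#'
#' @param mask logical matrix.
#' @param k number of components to keep (default 5).
#' @return logical matrix containing at most k components.
#' @export
keepLargestComponents <- function(mask, k = 5L) {
  if (!any(mask)) return(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- order(-sizes, seq_along(sizes))[seq_len(min(k, length(sizes)))]
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Pooled intensity statistics of a set of training ROIs
#'
#' @param images list of matrices in [0, 255].
#' @return \code{list(median, iqr)} over the pooled pixels.
#' @export
trainingRoiStats <- function(images) {
  v <- unlist(lapply(images, as.numeric), use.names = FALSE)
  list(median = median(v), iqr = IQR(v))
}

#' Preprocess an ROI for localization
#'
#' The enhancement chain applied before shape fitting: optional intensity
#' normalization against pooled training-ROI statistics (median/IQR matching),
#' contrast-limited adaptive histogram equalization, saturation of the darkest
#' and brightest 1\% of intensities (with a stretch back to [0, 255]), then
#' Otsu binarization of the dark class keeping at most the five largest
#' connected components.
#'
#' @param image matrix in [0, 255].
#' @param ref_stats optional \code{\link{trainingRoiStats}} result; NULL skips
#'   normalization.
#' @param keep number of connected components retained (default 5).
#' @param saturate tail fraction clipped on each side (default 0.01).
#' @return \code{list(image, mask, flag)}: the enhanced integer image, the
#'   binary foreground mask, and a character flag ("" when clean, "constant"
#'   when Otsu was undefined, in which case the mask is empty).
#' @export
preprocessRoi <- function(image, ref_stats = NULL, keep = 5L,
                          saturate = 0.01) {
  assertGrayImage(image)
  img <- image
  if (diff(range(img)) == 0)
    return(list(image = matrix(as.integer(img), nrow(img), ncol(img)),
                mask = matrix(FALSE, nrow(img), ncol(img)),
                flag = "constant"))
  if (!is.null(ref_stats)) {
    m <- median(img); iq <- IQR(img)
    if (iq > 0)
      img <- (img - m) / iq * ref_stats$iqr + ref_stats$median
    img <- clamp(img, 0, 255)
  }
  # tile count adapts to small ROIs (CLAHE needs several pixels per tile)
  nx <- max(1L, min(8L, nrow(img) %/% 8L, ncol(img) %/% 8L))
  if (nx > 1L) {
    eq <- EBImage::clahe(EBImage::Image(img / 255), nx = nx, ny = nx,
                         bins = 256L, limit = 2)
    img <- clamp(as.numeric(EBImage::imageData(eq)), 0, 1) * 255
    img <- matrix(img, nrow(image), ncol(image))
  }
  qs <- quantile(img, c(saturate, 1 - saturate), names = FALSE)
  if (qs[2] > qs[1])
    img <- (clamp(img, qs[1], qs[2]) - qs[1]) / (qs[2] - qs[1]) * 255
  img <- matrix(as.integer(round(img)), nrow(image), ncol(image))

  mask <- otsuSegment(img)
  flag <- attr(mask, "flag")
  mask <- keepLargestComponents(mask, k = keep)
  list(image = img, mask = mask, flag = flag)
}
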