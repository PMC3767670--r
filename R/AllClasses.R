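#' @include utils.R
NULL

#' The 13 hippocampal sub-region names
#'
#' Canonical region order used everywhere in the package: four CA1 regions,
#' four CA3 regions and five dentate-gyrus regions. The "a" regions are the
#' cell-body band cores (stratum pyramidale / stratum granulosum), "b"/"c" the
#' lateral band flanks, and "d" (plus "e" for the DG) the flanking neuropil
#' strips.
#'
#' @return character vector of length 13.
#' @export
regionNamesCanonical <- function() {
  c("CA1a", "CA1b", "CA1c", "CA1d",
    "CA3a", "CA3b", "CA3c", "CA3d",
    "DGa", "DGb", "DGc", "DGd", "DGe")
}

#' ShapeModel: deformable point model of AH and DG
#'
#' Point-distribution model in the Active Shape Model tradition: a mean shape
#' of 15 landmarks (8 on the Ammon's-horn pyramidal band midline followed by 7
#' on the dentate-gyrus granular band midline), principal deformation modes,
#' and per-mode standard deviations bounding admissible coefficients.
#'
#' @slot meanShape 15 x 2 matrix of (row, col) landmarks, centroid at origin.
#' @slot modes 30 x k matrix; each column a deformation direction over the
#'   stacked (row, col) coordinates.
#' @slot sdev length-k standard deviations; coefficients are bounded at
#'   \code{modeBoundSd} standard deviations.
#' @slot modeBoundSd scalar bound (in SDs) on mode coefficients, default 3.
#' @slot refScale centroid size of the mean shape (pixels), used to express
#'   the pose scale around 1.
#' @export
setClass("ShapeModel",
  representation(meanShape = "matrix", modes = "matrix", sdev = "numeric",
                 modeBoundSd = "numeric", refScale = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@meanShape) == c(15L, 2L)))
      msg <- c(msg, "meanShape must be a 15 x 2 matrix (8 AH + 7 DG points)")
    if (nrow(object@modes) != 30L)
      msg <- c(msg, "modes must have 30 rows (stacked coordinates)")
    if (ncol(object@modes) != length(object@sdev))
      msg <- c(msg, "one sdev per mode is required")
    if (length(object@sdev) && any(object@sdev < 0))
      msg <- c(msg, "sdev must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' LocalizationResult: fitted AH/DG control points
#'
#' @slot ahPoints 8 x 2 matrix of fitted Ammon's-horn points (row, col).
#' @slot dgPoints 7 x 2 matrix of fitted dentate-gyrus points.
#' @slot energy scalar energy of the fit (lower is better).
#' @slot roi bounding box used, c(row0, row1, col0, col1), 1-based closed.
#' @slot atlasLevel integer atlas level in [117, 175] (NA when unknown).
#' @slot success FALSE when localization failed (blank image, empty mask).
#' @export
setClass("LocalizationResult",
  representation(ahPoints = "matrix", dgPoints = "matrix", energy = "numeric",
                 roi = "numeric", atlasLevel = "integer", success = "logical"),
  prototype(atlasLevel = NA_integer_, success = TRUE),
  validity = function(object) {
    msg <- NULL
    if (object@success) {
      if (!all(dim(object@ahPoints) == c(8L, 2L)))
        msg <- c(msg, "ahPoints must be 8 x 2")
      if (!all(dim(object@dgPoints) == c(7L, 2L)))
        msg <- c(msg, "dgPoints must be 7 x 2")
      if (length(object@roi) != 4L)
        msg <- c(msg, "roi must be c(row0, row1, col0, col1)")
    }
    if (!is.na(object@atlasLevel) &&
        (object@atlasLevel < 117L || object@atlasLevel > 175L))
      msg <- c(msg, "atlasLevel must lie in [117, 175]")
    if (is.null(msg)) TRUE else msg
  })

#' RegionSet: the 13 named sub-region masks of one section
#'
#' Masks are stored as vectors of linear pixel indices into an image of
#' dimension \code{dim}; they are pairwise disjoint by construction and
#' validity.
#'
#' @slot dim image dimension c(nrow, ncol).
#' @slot regions named list of 13 integer vectors (linear pixel indices).
#' @slot boxes named list of the three source boxes (CA1, CA3, DG), each
#'   c(row0, row1, col0, col1).
#' @slot flags character vector of non-fatal warnings raised while building.
#' @export
setClass("RegionSet",
  representation(dim = "integer", regions = "list", boxes = "list",
                 flags = "character"),
  prototype(flags = character()),
  validity = function(object) {
    msg <- NULL
    if (length(object@dim) != 2L) msg <- c(msg, "dim must be length 2")
    if (!identical(names(object@regions), regionNamesCanonical()))
      msg <- c(msg, "regions must be named by the 13 canonical region names")
    idx <- unlist(object@regions, use.names = FALSE)
    if (length(idx)) {
      if (any(idx < 1L | idx > prod(object@dim)))
        msg <- c(msg, "region indices outside the image")
      if (anyDuplicated(idx))
        msg <- c(msg, "region masks must be pairwise disjoint")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ShapeModel", function(object) {
  cat("ShapeModel: 8 AH + 7 DG landmarks,", ncol(object@modes),
      "deformation mode(s), coefficient bound ±", object@modeBoundSd, "SD\n")
})

setMethod("show", "LocalizationResult", function(object) {
  if (!object@success) {
    cat("LocalizationResult: FAILED\n"); return(invisible(NULL))
  }
  cat(sprintf("LocalizationResult: energy %.4f, atlas level %s\n",
              object@energy,
              ifelse(is.na(object@atlasLevel), "<unset>", object@atlasLevel)))
})

setMethod("show", "RegionSet", function(object) {
  n <- vapply(object@regions, length, integer(1))
  cat(sprintf("RegionSet on a %d x %d image; 13 regions, %d--%d px each\n",
              object@dim[1], object@dim[2], min(n), max(n)))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @describeIn RegionSet-class names of the 13 regions (canonical order).
#' @param x a \code{RegionSet}.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname RegionSet-class
#' @export
setMethod("regionNames", "RegionSet", function(x) names(x@regions))

#' Extract one region as a logical mask matrix
#'
#' @param x a \code{RegionSet}.
#' @param name one of the 13 canonical region names.
#' @return logical matrix of dimension \code{dim(x)}.
#' @export
setGeneric("regionMask", function(x, name) standardGeneric("regionMask"))

#' @rdname regionMask
#' @export
setMethod("regionMask", "RegionSet", function(x, name) {
  name <- match.arg(name, regionNamesCanonical())
  m <- matrix(FALSE, x@dim[1], x@dim[2])
  m[x@regions[[name]]] <- TRUE
  m
})

#' Fitted control points of a localization result
#'
#' @param x a \code{LocalizationResult}.
#' @return 15 x 2 matrix (8 AH rows then 7 DG rows) or NULL on failure.
#' @export
setGeneric("controlPoints", function(x) standardGeneric("controlPoints"))

#' @rdname controlPoints
#' @export
setMethod("controlPoints", "LocalizationResult", function(x) {
  if (!x@success) return(NULL)
  rbind(x@ahPoints, x@dgPoints)
})

# internal constructor used by segmentation code
newRegionSet <- function(dim, regions, boxes = list(), flags = character()) {
  new("RegionSet", dim = as.integer(dim), regions = regions,
      boxes = boxes, flags = flags)
}
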