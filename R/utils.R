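# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Stable integer hash so that every stochastic stage of the pipeline consumes
#' an independent, reproducible stream derived from one master seed. Kept
#' below 2^31 - 1 so the result is always a valid R integer.
#'
#' @param seed master seed (single integer).
#' @param tag integer tag distinguishing the consumer.
#' @return a single integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, length(tag) == 1L, is.finite(seed), is.finite(tag))
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  # two rounds of a multiplicative congruence keep streams for nearby tags apart
  x <- (x * 48271 + as.numeric(tag) * 16807 + 1) %% m
  x <- (x * 69621 + 7) %% m
  as.integer(x)
}

# run expr with a local RNG state (does not disturb the caller's stream)
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# validate an 8-bit grayscale image stored as a numeric/integer matrix in [0,255]
assertGrayImage <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 255)
    stop("image must be a finite matrix with values in [0, 255]")
  invisible(image)
}

# bilinear interpolation of matrix `m` at (possibly fractional) rows/cols;
# points outside return `fill`
bilinearSample <- function(m, r, c, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0
  v <- m[i00]       * (1 - fr) * (1 - fc) +
       m[i00 + 1]   * fr       * (1 - fc) +
       m[i00 + H]   * (1 - fr) * fc +
       m[i00 + H + 1] * fr     * fc
  out[ok] <- v
  out
}

# nearest-pixel lookup with out-of-image fill
nearestSample <- function(m, r, c, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  ri <- round(r); ci <- round(c)
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out <- rep(fill, length(r))
  if (any(ok)) out[ok] <- m[cbind(ri[ok], ci[ok])]
  out
}

# clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
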