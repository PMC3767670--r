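#' @include selection.R
NULL

#' Pre-filter probes on reported expression
#'
#' Retains probes whose reported hippocampal expression level OR expression
#' density is strictly above the threshold (default 20, the background level
#' below which genes are considered silent in adult brain). Probes missing
#' both values are excluded with a warning.
#'
#' @param metadata data frame with columns \code{probe},
#'   \code{expression_level} and \code{expression_density} (NA allowed).
#' @param threshold strict lower cutoff (default 20).
#' @return character vector of retained probe ids.
#' @export
expressionFilter <- function(metadata, threshold = 20) {
  stopifnot(all(c("probe", "expression_level", "expression_density") %in%
                  names(metadata)))
  lev <- metadata$expression_level
  den <- metadata$expression_density
  bothMissing <- is.na(lev) & is.na(den)
  if (any(bothMissing))
    warning(sum(bothMissing),
            " probe(s) excluded: no expression level or density reported")
  keep <- !bothMissing &
    ((!is.na(lev) & lev > threshold) | (!is.na(den) & den > threshold))
  as.character(metadata$probe[keep])
}

#' Pearson correlation with degenerate-input convention
#'
#' Standard product-moment correlation; when either vector has zero variance
#' the value is defined as 0 and flagged.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return scalar r in [-1, 1], with attribute "flag" = "zero_variance" in
#'   the degenerate case.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0 || sd(y) == 0) {
    r <- 0
    attr(r, "flag") <- "zero_variance"
    return(r)
  }
  cor(x, y)
}

#' Prototype vector from the positive training sections
#'
#' Features are z-scored with the training-set column means/SDs, restricted to
#' the consensus mask, and averaged over the positive sections. The z-scoring
#' parameters are stored so screened genes are standardized identically.
#'
#' @param train a \code{\link{trainingSet}}.
#' @param mask logical consensus mask over the training columns (from
#'   \code{\link{consensusSelect}}).
#' @return \code{list(values, features, center, scale)} of class
#'   \code{PrototypeVector}.
#' @export
prototypeVector <- function(train, mask) {
  stopifnot(length(mask) == ncol(train$X), any(mask))
  center <- colMeans(train$X)
  scale <- apply(train$X, 2L, sd)
  Xz <- zscoreMatrix(train$X, center, scale)
  vals <- colMeans(Xz[train$labels == "positive", mask, drop = FALSE])
  structure(list(values = vals, features = colnames(train$X)[mask],
                 center = center[mask], scale = scale[mask]),
            class = "PrototypeVector")
}

#' Rank genes by Pearson similarity to the prototype
#'
#' Each probe's feature vector is restricted to the selected features,
#' z-scored with the training parameters, and correlated with the prototype.
#' Rows are sorted by r descending with ties broken by probe id; the r >= 0.8
#' and r >= 0.7 candidate cut lines are reported as columns.
#'
#' @param features numeric matrix, one row per probe, columns a superset of
#'   the prototype's features; rownames are probe ids.
#' @param prototype a \code{\link{prototypeVector}}.
#' @param metadata optional data frame with columns \code{probe},
#'   \code{gene} and \code{atlas_level} merged into the output.
#' @param cuts reportable r cut lines (default c(0.8, 0.7)).
#' @return data frame (RankingTable) with columns gene, probe, atlas_level,
#'   r, rank, pass_0.8, pass_0.7.
#' @export
rankGenes <- function(features, prototype, metadata = NULL,
                      cuts = c(0.8, 0.7)) {
  missing <- setdiff(prototype$features, colnames(features))
  if (length(missing))
    stop("feature table lacks selected columns: ",
         paste(head(missing, 5L), collapse = ", "))
  probes <- rownames(features)
  if (is.null(probes)) probes <- sprintf("probe%03d", seq_len(nrow(features)))
  Xs <- features[, prototype$features, drop = FALSE]
  scl <- prototype$scale
  scl[scl == 0] <- 1
  Xz <- sweep(sweep(Xs, 2L, prototype$center), 2L, scl, "/")
  r <- apply(Xz, 1L, function(z) as.numeric(pearson(z, prototype$values)))
  ord <- order(-r, probes)
  tab <- data.frame(probe = probes[ord], r = r[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  for (ct in cuts)
    tab[[sprintf("pass_%.1f", ct)]] <- tab$r >= ct
  if (!is.null(metadata)) {
    md <- metadata[match(tab$probe, metadata$probe), , drop = FALSE]
    tab$gene <- md$gene
    tab$atlas_level <- md$atlas_level
  } else {
    tab$gene <- tab$probe
    tab$atlas_level <- NA_integer_
  }
  tab[, c("gene", "probe", "atlas_level", "r", "rank",
          sprintf("pass_%.1f", cuts))]
}

#' Cross-level stability of a gene's similarity score
#'
#' Given the r values of one gene computed from sections at several atlas
#' levels, reports min / median / max / IQR. Genes with fewer than two
#' accepted sections get a flagged single-value summary.
#'
#' @param rValues named list: per gene, the numeric vector of section r's.
#' @return data frame with one row per gene: gene, n, min, median, max, iqr,
#'   flag.
#' @export
stabilityProfile <- function(rValues) {
  rows <- lapply(names(rValues), function(g) {
    r <- rValues[[g]]
    flag <- if (length(r) < 2L) "single_section" else ""
    data.frame(gene = g, n = length(r), min = min(r), median = median(r),
               max = max(r), iqr = if (length(r) < 2L) 0 else IQR(r),
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
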