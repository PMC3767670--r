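#' @include utils.R
NULL

#' Relative expression by the 2^-dCt method
#'
#' dCt is the target's Ct minus the reference gene's Ct (Fmr1 in the
#' validation design, present at equal levels in synaptosomes and whole
#' brain); expression in arbitrary units is 2^-dCt. Not-detected (NA) targets
#' propagate to NA.
#'
#' @param ct_target target Ct values (cycles; NA = not detected).
#' @param ct_reference reference-gene Ct values.
#' @return numeric vector of relative expression (arbitrary units).
#' @export
relativeExpression <- function(ct_target, ct_reference) {
  if (length(ct_reference) == 1L)
    ct_reference <- rep(ct_reference, length(ct_target))
  stopifnot(length(ct_target) == length(ct_reference))
  ok <- !is.na(ct_target) & !is.na(ct_reference)
  if (any(ct_target[ok] <= 0 | ct_reference[ok] <= 0))
    stop("Ct values must be positive")
  2^(-(ct_target - ct_reference))
}

#' Synaptosome / total-brain enrichment ratio
#'
#' Ratio of relative expression (2^-dCt units) between the synaptosomal and
#' total-brain compartments. NA (not detected) in either compartment
#' propagates.
#'
#' @param synaptosomal,brain relative-expression values (arbitrary units).
#' @return \code{list(ratio, rounded)}: full-precision ratio and its 2-decimal
#'   presentation.
#' @export
enrichmentRatio <- function(synaptosomal, brain) {
  stopifnot(length(synaptosomal) == length(brain))
  bad <- !is.na(brain) & brain <= 0
  if (any(bad)) stop("brain levels must be > 0")
  ratio <- synaptosomal / brain
  list(ratio = ratio, rounded = round(ratio, 2L))
}

#' Summarize a qPCR replicate table into per-gene enrichment ratios
#'
#' Aggregates replicates by mean (sample SD reported alongside), computes
#' 2^-dCt per compartment and the synaptosome/brain ratio. A gene not
#' detected in either compartment gets an NA ratio.
#'
#' @param ct data frame with columns gene, compartment ("synaptosome" or
#'   "brain"), replicate, ct_target, ct_reference; NA Ct = not detected.
#' @return data frame: gene, synaptosomal_au, synaptosomal_sd, brain_au,
#'   brain_sd, ratio (2 decimals), ratio_full.
#' @export
qpcrTable <- function(ct) {
  stopifnot(all(c("gene", "compartment", "replicate", "ct_target",
                  "ct_reference") %in% names(ct)),
            all(ct$compartment %in% c("synaptosome", "brain")))
  ct$au <- relativeExpression(ct$ct_target, ct$ct_reference)
  agg <- function(comp, fun) {
    sub <- ct[ct$compartment == comp, ]
    out <- tapply(sub$au, sub$gene, fun)
    out[match(unique(ct$gene), names(out))]
  }
  genes <- unique(ct$gene)
  synMean <- agg("synaptosome", function(v) mean(v))
  synSd <- agg("synaptosome", function(v) if (length(v) > 1) sd(v) else NA)
  brMean <- agg("brain", function(v) mean(v))
  brSd <- agg("brain", function(v) if (length(v) > 1) sd(v) else NA)
  er <- enrichmentRatio(unname(synMean), unname(brMean))
  data.frame(gene = genes,
             synaptosomal_au = unname(synMean),
             synaptosomal_sd = unname(synSd),
             brain_au = unname(brMean),
             brain_sd = unname(brSd),
             ratio = er$rounded,
             ratio_full = er$ratio,
             stringsAsFactors = FALSE)
}
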