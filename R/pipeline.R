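#' @include synthetic.R segment.R texture.R ranking.R
NULL

#' Full pipeline configuration
#'
#' Bundles every stage's parameters around one master seed. Thresholds carried
#' here: feature-dedup correlation 0.99, expression pre-filter 20, reportable
#' ranking cut lines r >= 0.8 and r >= 0.7, atlas range 117--175 with default
#' level 145.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_train_pos,n_train_neg training cohort composition (3 / 17).
#' @param n_screen size of the graded screen (30).
#' @param e_pos,e_neg,e_screen enrichment ranges of positives, negatives and
#'   the screen grading.
#' @param base_params template \code{\link{sectionParams}}.
#' @param de,ga \code{\link{deParams}} / \code{\link{gaParams}}.
#' @param dedup_threshold,expression_threshold,cuts pipeline thresholds.
#' @param default_level,atlas_range atlas slice policy.
#' @param out_dir optional artifact directory; NULL writes nothing.
#' @return configuration list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L, n_train_pos = 3L, n_train_neg = 17L,
                           n_screen = 30L, e_pos = c(1.2, 1.6),
                           e_neg = c(0, 0.3), e_screen = c(0, 2),
                           base_params = sectionParams(),
                           de = deParams(), ga = gaParams(),
                           dedup_threshold = 0.99,
                           expression_threshold = 20,
                           cuts = c(0.8, 0.7),
                           default_level = 145L,
                           atlas_range = c(117L, 175L),
                           out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_train_pos = n_train_pos,
                 n_train_neg = n_train_neg, n_screen = n_screen,
                 e_pos = e_pos, e_neg = e_neg, e_screen = e_screen,
                 base_params = base_params, de = de, ga = ga,
                 dedup_threshold = dedup_threshold,
                 expression_threshold = expression_threshold, cuts = cuts,
                 default_level = default_level, atlas_range = atlas_range,
                 out_dir = out_dir),
            class = "PipelineConfig")
}

# localize + segment + QC one section; returns a RegionSet or a
# segmentationFailure carrying the discard reason
segmentSection <- function(image, model, rfInside, rfAccept, de, seed) {
  pre <- preprocessRoi(image)
  if (!any(pre$mask))
    return(segFailure("empty foreground"))
  deSec <- de
  deSec$seed <- deriveSeed(seed, 1L)
  loc <- fitShape(image, model, de = deSec, pre = pre)
  if (!loc@success)
    return(segFailure("localization failed"))
  boxes <- selectAreas(loc)
  regions <- partitionRegions(boxes, image,
                              inward = colMeans(controlPoints(loc)))
  if (segmentationFailed(regions)) return(regions)
  qc <- qcSegmentation(image, regions, rfInside, rfAccept,
                       seed = deriveSeed(seed, 2L))
  if (!qc$accepted) return(segFailure("QC rejected"))
  attr(regions, "qc") <- qc
  attr(regions, "loc") <- loc
  regions
}

#' Run the full screen end to end
#'
#' Stages, each on a seed derived from the master seed: (1) simulate the
#' labeled training cohort and the graded screen; (2) build the shape model
#' from the training ground-truth shapes and train the two QC forests; (3)
#' localize, partition and QC every section, discarding failures with a
#' logged reason; (4) extract the 220-feature texture vectors; (5) dedup +
#' GA-consensus feature selection on the training cohort and build the
#' prototype; (6) apply the expression pre-filter and rank the screen by
#' Pearson similarity. Re-running with the same master seed reproduces every
#' artifact byte for byte.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list with elements \code{ranking} (RankingTable data frame),
#'   \code{consensus}, \code{prototype}, \code{train_features},
#'   \code{screen_features}, \code{screen_truth} (planted enrichment),
#'   \code{discards} (data frame id/stage/reason), \code{log} (character),
#'   and \code{paths} when artifacts were written.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  seed <- config$seed
  logLines <- character()
  say <- function(...) {
    logLines <<- c(logLines, sprintf(...))
  }

  say("master seed: %d", seed)
  train <- generateCohort(config$n_train_pos, config$n_train_neg,
                          config$e_pos, config$e_neg,
                          seed = deriveSeed(seed, 1L),
                          base_params = config$base_params)
  screen <- generateScreen(config$n_screen, config$e_screen,
                           seed = deriveSeed(seed, 2L),
                           base_params = config$base_params)
  say("simulated %d training and %d screen sections",
      length(train), length(screen))

  shapes <- lapply(train, function(s) rbind(s$truth$ahPoints,
                                            s$truth$dgPoints))
  model <- buildShapeModel(shapes)
  rfInside <- trainInsideForest(train, seed = deriveSeed(seed, 3L))
  rfAccept <- trainAcceptForest(train, rfInside, seed = deriveSeed(seed, 4L))
  say("shape model: %d mode(s); QC forests trained", ncol(model@modes))

  discards <- data.frame(id = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)
  extractAll <- function(sections, tag) {
    feats <- list()
    for (i in seq_along(sections)) {
      sec <- sections[[i]]
      regions <- segmentSection(sec$image, model, rfInside, rfAccept,
                                config$de,
                                seed = deriveSeed(seed, 100L * i + 5L))
      if (segmentationFailed(regions)) {
        reason <- regions$reason
        say("%s %s discarded: %s", tag, sec$id, reason)
        discards <<- rbind(discards,
                           data.frame(id = sec$id, stage = tag,
                                      reason = reason,
                                      stringsAsFactors = FALSE))
        next
      }
      feats[[sec$id]] <- assembleFeatureVector(sec$image, regions)
    }
    if (!length(feats)) return(NULL)
    do.call(rbind, feats)
  }

  trainX <- extractAll(train, "train")
  screenX <- extractAll(screen, "screen")
  if (is.null(trainX) || is.null(screenX))
    stop("pipeline aborted: no section survived segmentation")
  trainLabels <- vapply(train, `[[`, character(1), "label")
  names(trainLabels) <- vapply(train, `[[`, character(1), "id")
  trainLabels <- trainLabels[rownames(trainX)]
  say("features: %d train x %d, %d screen", nrow(trainX), ncol(trainX),
      nrow(screenX))

  ts <- trainingSet(trainX, trainLabels)
  dd <- dedupFeatures(ts, config$dedup_threshold)
  tsRed <- trainingSet(trainX[, dd$kept, drop = FALSE], trainLabels)
  say("dedup: %d of %d features kept (|r| > %.2f collapsed)",
      length(dd$kept), ncol(trainX), config$dedup_threshold)
  gaCfg <- config$ga
  gaCfg$seed <- deriveSeed(seed, 6L)
  consensus <- consensusSelect(tsRed, gaCfg)
  say("consensus: %d features selected in >= %d of %d runs",
      sum(consensus$selected), consensus$threshold_runs, consensus$runs)
  proto <- prototypeVector(tsRed, consensus$selected)

  # reported metadata mirrors what an atlas would publish per probe: a
  # signal-derived expression level and density (both clear the >20 filter
  # for expressed genes)
  metadata <- data.frame(
    probe = rownames(screenX),
    gene = rownames(screenX),
    atlas_level = config$default_level,
    expression_level = round(100 * (1 - screenX[, "CA1a_w18_mean"] / 255), 1),
    expression_density = round(100 * (1 - screenX[, "DGa_w18_mean"] / 255), 1),
    stringsAsFactors = FALSE)
  kept <- expressionFilter(metadata, config$expression_threshold)
  say("expression filter (>%g): %d of %d probes retained",
      config$expression_threshold, length(kept), nrow(metadata))
  for (pr in setdiff(rownames(screenX), kept))
    discards <- rbind(discards,
                      data.frame(id = pr, stage = "filter",
                                 reason = "expression <= threshold",
                                 stringsAsFactors = FALSE))

  ranking <- rankGenes(screenX[kept, , drop = FALSE], proto,
                       metadata = metadata, cuts = config$cuts)

  screenTruth <- data.frame(
    probe = vapply(screen, `[[`, character(1), "id"),
    enrichment = vapply(screen, `[[`, numeric(1), "enrichment"),
    stringsAsFactors = FALSE)

  out <- list(ranking = ranking, consensus = consensus, prototype = proto,
              train_features = trainX, screen_features = screenX,
              screen_truth = screenTruth, discards = discards,
              model = model, log = logLines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) {
      p <- file.path(config$out_dir, f)
      write.table(format(x, digits = 12, trim = TRUE), p, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      p
    }
    paths <- c(
      ranking = wt(ranking, "ranking.tsv"),
      consensus = wt(data.frame(feature = names(consensus$frequency),
                                frequency = consensus$frequency,
                                selected = consensus$selected,
                                row.names = NULL),
                     "consensus_mask.tsv"),
      train_features = wt(data.frame(id = rownames(trainX), trainX,
                                     check.names = FALSE, row.names = NULL),
                          "train_features.tsv"),
      screen_features = wt(data.frame(id = rownames(screenX), screenX,
                                      check.names = FALSE, row.names = NULL),
                           "screen_features.tsv"),
      discards = wt(discards, "discards.tsv"))
    writeLines(logLines, file.path(config$out_dir, "run.log"))
    out$paths <- c(paths, log = file.path(config$out_dir, "run.log"))
  }
  out
}
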