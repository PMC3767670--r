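#' @include utils.R
NULL

#' Genetic-algorithm settings for feature selection
#'
#' Defaults are the screen's settings: population 50, 300 generations,
#' one-point crossover at rate 0.8, per-bit mutation 0.06, tournament
#' selection of size 4, 15 repeated runs with a >= 50\% consensus.
#'
#' @param population,generations GA size and length.
#' @param crossover_rate,mutation_rate rates in [0, 1].
#' @param tournament_size tournament size (<= population).
#' @param runs number of repeated runs feeding the consensus.
#' @param consensus_threshold minimum fraction of runs a feature must be
#'   selected in (>= 50\% of 15 runs means >= 8 runs).
#' @param seed integer master seed; run seeds are derived from it.
#' @return parameter list of class \code{GAParams}.
#' @export
gaParams <- function(population = 50L, generations = 300L,
                     crossover_rate = 0.8, mutation_rate = 0.06,
                     tournament_size = 4L, runs = 15L,
                     consensus_threshold = 0.5, seed = 1L) {
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament_size <= population, runs >= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 runs = as.integer(runs),
                 consensus_threshold = consensus_threshold,
                 seed = as.integer(seed)),
            class = "GAParams")
}

#' Assemble a training set for feature selection
#'
#' @param X numeric matrix, one row per training section, columns named by
#'   feature; at least 2 positives and 2 negatives are required (the
#'   silhouette needs within-group distances).
#' @param labels character/factor of "positive"/"negative" per row.
#' @return \code{list(X, labels)} of class \code{TrainingSet}.
#' @export
trainingSet <- function(X, labels) {
  labels <- as.character(labels)
  stopifnot(is.matrix(X), nrow(X) == length(labels),
            !is.null(colnames(X)),
            all(labels %in% c("positive", "negative")))
  if (sum(labels == "positive") < 2L || sum(labels == "negative") < 2L)
    stop("need at least 2 positives and 2 negatives")
  structure(list(X = X, labels = labels), class = "TrainingSet")
}

#' Drop near-duplicate features (|r| > threshold)
#'
#' Greedy pass in canonical column order: a feature is dropped when its
#' absolute Pearson correlation with an already-kept feature exceeds the
#' threshold over the training rows. Zero-variance features have undefined
#' correlation and are all treated as duplicates of the first zero-variance
#' feature kept.
#'
#' @param train a \code{\link{trainingSet}}.
#' @param threshold correlation cutoff (default 0.99, strict inequality).
#' @return \code{list(kept, dropped)}: kept feature names in order, and a
#'   named character vector mapping each dropped feature to the kept feature
#'   that absorbed it.
#' @export
dedupFeatures <- function(train, threshold = 0.99) {
  X <- train$X
  stopifnot(nrow(X) >= 2L)
  sds <- apply(X, 2L, sd)
  kept <- character(0)
  dropped <- character(0)
  firstZeroVar <- NA_character_
  keptMat <- NULL
  for (nm in colnames(X)) {
    if (sds[nm] == 0) {
      if (is.na(firstZeroVar)) {
        firstZeroVar <- nm
        kept <- c(kept, nm)
      } else {
        dropped[nm] <- firstZeroVar
      }
      next
    }
    if (length(kept)) {
      keepSd <- sds[kept] > 0
      if (any(keepSd)) {
        rs <- abs(cor(X[, nm], X[, kept[keepSd], drop = FALSE]))
        hit <- which(rs > threshold)
        if (length(hit)) {
          dropped[nm] <- kept[keepSd][hit[1]]
          next
        }
      }
    }
    kept <- c(kept, nm)
  }
  list(kept = kept, dropped = dropped)
}

# z-score columns with given (or own) centers/scales; zero scales pass through
zscoreMatrix <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2L, sd)
  scale[scale == 0] <- 1
  sweep(sweep(X, 2L, center), 2L, scale, "/")
}

# silhouette of a z-scored matrix restricted to `mask` columns; Euclidean
# distances via the Gram matrix, fully vectorized (the GA evaluates this tens
# of thousands of times)
silhouetteOnZ <- function(Xz, pos, mask) {
  if (!any(mask)) return(-1)
  Xs <- Xz[, mask, drop = FALSE]
  G <- tcrossprod(Xs)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  npos <- sum(pos); nneg <- length(pos) - npos
  sumPos <- rowSums(D[, pos, drop = FALSE])
  sumNeg <- rowSums(D[, !pos, drop = FALSE])
  a <- ifelse(pos, sumPos / (npos - 1), sumNeg / (nneg - 1))
  b <- ifelse(pos, sumNeg / nneg, sumPos / npos)
  mx <- pmax(a, b)
  mean(ifelse(mx == 0, 0, (b - a) / mx))
}

#' Silhouette fitness of a feature subset
#'
#' Mean silhouette s = (b - a) / max(a, b) over the training sections, with a
#' the mean Euclidean distance of a section to its own group (excluding
#' itself) and b its mean distance to the other group. Distances are computed
#' over the selected features after z-scoring each feature on the training
#' set. An element with max(a, b) = 0 contributes s = 0; an empty mask scores
#' -1 (worst).
#'
#' @param mask logical vector over the columns of the training matrix.
#' @param train a \code{\link{trainingSet}}.
#' @return scalar in [-1, 1].
#' @export
silhouetteFitness <- function(mask, train) {
  stopifnot(length(mask) == ncol(train$X))
  silhouetteOnZ(zscoreMatrix(train$X), train$labels == "positive", mask)
}

#' One binary-GA run of feature selection
#'
#' Binary-encoded individuals scored by \code{\link{silhouetteFitness}};
#' tournament selection, one-point crossover, per-bit flip mutation,
#' generational replacement with single-individual elitism. All-zero
#' individuals score -1 and are never returned as best. Deterministic given
#' \code{run_seed}.
#'
#' @param train a \code{\link{trainingSet}} (typically after
#'   \code{\link{dedupFeatures}}).
#' @param ga \code{\link{gaParams}}.
#' @param run_seed seed of this run.
#' @return \code{list(bits, fitness)}: logical mask over columns and its
#'   silhouette fitness.
#' @export
gaRun <- function(train, ga = gaParams(), run_seed = 1L) {
  Xz <- zscoreMatrix(train$X)
  pos <- train$labels == "positive"
  p <- ncol(Xz)
  NP <- ga$population
  evalMask <- function(bits) silhouetteOnZ(Xz, pos, bits)
  withSeed(run_seed, {
    popn <- matrix(runif(NP * p) < 0.5, NP, p)
    fit <- apply(popn, 1L, evalMask)
    bestBits <- popn[which.max(fit), ]
    bestFit <- max(fit)
    for (g in seq_len(ga$generations)) {
      tournament <- function() {
        cand <- sample.int(NP, ga$tournament_size)
        cand[which.max(fit[cand])]
      }
      children <- matrix(FALSE, NP, p)
      for (i in seq(1L, NP, by = 2L)) {
        pa <- popn[tournament(), ]
        pb <- popn[tournament(), ]
        if (runif(1) < ga$crossover_rate && p > 1L) {
          cut <- sample.int(p - 1L, 1L)
          c1 <- c(pa[1:cut], pb[(cut + 1L):p])
          c2 <- c(pb[1:cut], pa[(cut + 1L):p])
        } else {
          c1 <- pa; c2 <- pb
        }
        children[i, ] <- c1
        if (i + 1L <= NP) children[i + 1L, ] <- c2
      }
      if (ga$mutation_rate > 0) {
        flips <- matrix(runif(NP * p) < ga$mutation_rate, NP, p)
        children <- xor(children, flips)
      }
      children[1L, ] <- bestBits       # keep-1 elitism
      popn <- children
      fit <- apply(popn, 1L, evalMask)
      if (max(fit) > bestFit) {
        bestFit <- max(fit)
        bestBits <- popn[which.max(fit), ]
      }
    }
    list(bits = bestBits, fitness = bestFit)
  })
}

#' Consensus feature selection over repeated GA runs
#'
#' Executes \code{ga$runs} independent GA runs with derived seeds and keeps
#' the features selected in at least \code{ceiling(runs *
#' consensus_threshold)} of them (>= 8 of 15 at the defaults). An empty
#' consensus falls back to the maximal-frequency features, flagged.
#'
#' @param train a \code{\link{trainingSet}}.
#' @param ga \code{\link{gaParams}}.
#' @return \code{list(selected, frequency, runs, threshold_runs, flag)}:
#'   selected is a logical mask over columns (named), frequency the per-
#'   feature selection count.
#' @export
consensusSelect <- function(train, ga = gaParams()) {
  masks <- vapply(seq_len(ga$runs), function(r)
    gaRun(train, ga, run_seed = deriveSeed(ga$seed, 8000L + r))$bits,
    logical(ncol(train$X)))
  freq <- rowSums(masks)
  names(freq) <- colnames(train$X)
  need <- as.integer(ceiling(ga$runs * ga$consensus_threshold))
  selected <- freq >= need
  flag <- ""
  if (!any(selected)) {
    selected <- freq == max(freq)
    flag <- "empty_consensus_fallback"
  }
  list(selected = selected, frequency = freq, runs = ga$runs,
       threshold_runs = need, flag = flag)
}
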