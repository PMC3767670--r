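#' @include utils.R
NULL

#' Differential Evolution settings
#'
#' Defaults are the settings used for shape-model fitting: DE/target-to-best/1
#' mutation with uniform crossover, crossover rate 0.9, scale factor F = 0.7,
#' 64 individuals and 200 generations.
#'
#' @param crossover_rate uniform-crossover probability in [0, 1].
#' @param F differential scale factor (> 0).
#' @param population number of individuals (>= 4).
#' @param generations number of generations (>= 0).
#' @param seed integer seed.
#' @return parameter list of class \code{DEParams}.
#' @export
deParams <- function(crossover_rate = 0.9, F = 0.7, population = 64L,
                     generations = 200L, seed = 1L) {
  stopifnot(crossover_rate >= 0, crossover_rate <= 1, F > 0, generations >= 0)
  structure(list(crossover_rate = crossover_rate, F = F,
                 population = as.integer(population),
                 generations = as.integer(generations),
                 seed = as.integer(seed)),
            class = "DEParams")
}

#' Particle Swarm Optimization settings
#'
#' Defaults are the registration settings: 24 particles, 40 iterations,
#' c1 = c2 = 2.05, inertia linearly decreasing from 1.0 to 0.1.
#'
#' @param particles swarm size (>= 2).
#' @param iterations iteration count (>= 1).
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param inertia c(start, end) with start > end; interpolated linearly so the
#'   first iteration uses \code{start} and the last uses \code{end}.
#' @param seed integer seed.
#' @return parameter list of class \code{PSOParams}.
#' @export
psoParams <- function(particles = 24L, iterations = 40L, c1 = 2.05, c2 = 2.05,
                      inertia = c(1.0, 0.1), seed = 1L) {
  stopifnot(particles >= 2, iterations >= 1, inertia[1] > inertia[2])
  structure(list(particles = as.integer(particles),
                 iterations = as.integer(iterations),
                 c1 = c1, c2 = c2, inertia = inertia,
                 seed = as.integer(seed)),
            class = "PSOParams")
}

#' Minimize an objective with DE/target-to-best/1
#'
#' Donor vectors follow \eqn{v_i = x_i + F (x_{best} - x_i) + F (x_{r1} -
#' x_{r2})} with r1, r2, i pairwise distinct, followed by uniform crossover
#' (one donor coordinate always inherited) and greedy one-to-one selection,
#' applied synchronously per generation. The returned value is never worse
#' than the best initial individual. Deterministic given the seed.
#'
#' @param objective function of a numeric vector, returns a scalar to
#'   minimize; must be evaluable everywhere inside the bounds.
#' @param lower,upper finite bound vectors of equal length.
#' @param params \code{\link{deParams}}.
#' @param init optional matrix (rows = individuals) seeded into the initial
#'   population.
#' @return \code{list(par, value)}.
#' @export
deOptimize <- function(objective, lower, upper, params = deParams(),
                       init = NULL) {
  D <- length(lower)
  stopifnot(length(upper) == D, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  NP <- params$population
  if (NP < 4L)
    stop("DE/target-to-best/1 needs a population of at least 4")
  CR <- params$crossover_rate; Fv <- params$F

  withSeed(params$seed, {
    X <- matrix(runif(NP * D, rep(lower, each = NP), rep(upper, each = NP)),
                NP, D)
    if (!is.null(init)) {
      init <- matrix(init, ncol = D)
      k <- min(nrow(init), NP)
      X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
    }
    fit <- apply(X, 1L, objective)
    lowM <- rep(lower, each = NP)
    uppM <- rep(upper, each = NP)
    idx <- seq_len(NP)
    for (g in seq_len(params$generations)) {
      xb <- X[which.min(fit), ]
      # r1, r2 distinct from each other and from the target index
      r1 <- sample.int(NP, NP, replace = TRUE)
      r2 <- sample.int(NP, NP, replace = TRUE)
      while (any(bad <- r1 == idx | r2 == idx | r1 == r2)) {
        r1[bad] <- sample.int(NP, sum(bad), replace = TRUE)
        r2[bad] <- sample.int(NP, sum(bad), replace = TRUE)
      }
      V <- X + Fv * (matrix(xb, NP, D, byrow = TRUE) - X) +
        Fv * (X[r1, , drop = FALSE] - X[r2, , drop = FALSE])
      V <- pmin(pmax(V, lowM), uppM)
      cross <- matrix(runif(NP * D) < CR, NP, D)
      cross[cbind(idx, sample.int(D, NP, replace = TRUE))] <- TRUE
      trial <- X
      trial[cross] <- V[cross]
      ftrial <- apply(trial, 1L, objective)
      upd <- ftrial <= fit
      X[upd, ] <- trial[upd, , drop = FALSE]
      fit[upd] <- ftrial[upd]
    }
    b <- which.min(fit)
    list(par = X[b, ], value = fit[b])
  })
}

#' Minimize an objective with canonical PSO
#'
#' Velocity update \eqn{v = w v + c_1 r_1 (p - x) + c_2 r_2 (g - x)} with the
#' inertia w interpolated linearly over iterations; positions are clamped to
#' the bounds. Velocities start at zero. Returns the swarm-best ever seen, so
#' the result is never worse than the best initial particle. Deterministic
#' given the seed.
#'
#' @inheritParams deOptimize
#' @param params \code{\link{psoParams}}.
#' @param init optional matrix of initial particle positions.
#' @return \code{list(par, value)}.
#' @export
psoOptimize <- function(objective, lower, upper, params = psoParams(),
                        init = NULL) {
  D <- length(lower)
  if (D == 0L) stop("empty bounds")
  stopifnot(length(upper) == D, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  NP <- params$particles
  withSeed(params$seed, {
    X <- matrix(runif(NP * D, rep(lower, each = NP), rep(upper, each = NP)),
                NP, D)
    if (!is.null(init)) {
      init <- matrix(init, ncol = D)
      k <- min(nrow(init), NP)
      X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
    }
    V <- matrix(0, NP, D)
    fit <- apply(X, 1L, objective)
    P <- X; pfit <- fit
    gb <- which.min(pfit)
    gpar <- P[gb, ]; gval <- pfit[gb]
    Tn <- params$iterations
    for (t in seq_len(Tn)) {
      w <- if (Tn == 1L) params$inertia[1] else
        params$inertia[1] + (params$inertia[2] - params$inertia[1]) *
          (t - 1) / (Tn - 1)
      r1 <- matrix(runif(NP * D), NP, D)
      r2 <- matrix(runif(NP * D), NP, D)
      V <- w * V + params$c1 * r1 * (P - X) +
        params$c2 * r2 * (matrix(gpar, NP, D, byrow = TRUE) - X)
      X <- clamp(X + V, rep(lower, each = NP), rep(upper, each = NP))
      fit <- apply(X, 1L, objective)
      upd <- fit < pfit
      P[upd, ] <- X[upd, ]; pfit[upd] <- fit[upd]
      b <- which.min(pfit)
      if (pfit[b] < gval) {
        gval <- pfit[b]; gpar <- P[b, ]
      }
    }
    list(par = gpar, value = gval)
  })
}

# inertia weight used at (1-based) iteration t of Tn; exported for clarity of
# the linear schedule
#' Linear inertia schedule
#'
#' @param t iteration (1-based), \code{Tn} total iterations.
#' @param Tn total iterations.
#' @param inertia c(start, end).
#' @return inertia weight at iteration t.
#' @export
psoInertiaAt <- function(t, Tn, inertia = c(1.0, 0.1)) {
  if (Tn == 1L) return(inertia[1])
  inertia[1] + (inertia[2] - inertia[1]) * (t - 1) / (Tn - 1)
}
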