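#' @importFrom stats rnorm runif sd quantile
NULL

# A particle is a plain list:
#   idx  - original index in the swarm
#   y    - personal best position,        fy  - its fitness
#   y2   - personal second-best position, fy2 - its fitness (fy <= fy2)
#   x    - current position (bookkeeping: the better of the particle's two
#          candidates from the last iteration; the memories drive the search)

newParticle <- function(idx, y, fy, y2, fy2) {
  list(idx = idx, y = y, fy = fy, y2 = y2, fy2 = fy2, x = y)
}

#' Initialize a dual-memory swarm
#'
#' Draws two uniform positions per particle inside the objective's box,
#' evaluates both, and seeds the particle's dual-layer memory: the position
#' with lower (or equal) fitness becomes the personal best `y`, the other
#' the personal second-best `y2`. The current position `x` is set to `y`.
#' Consumes exactly `2 * nParticles` objective evaluations.
#'
#' @param objective a [BoxObjective-class].
#' @param nParticles swarm size (at least 2).
#' @return list with elements `particles` (list of particle records) and
#'   `global` (the consolidated global memory, see
#'   [consolidateGlobalMemory()]).
#' @export
initializeSwarm <- function(objective, nParticles) {
  nParticles <- as.integer(nParticles)
  if (nParticles < 2L) stop("swarm needs at least 2 particles")
  d <- objective@dim
  particles <- vector("list", nParticles)
  for (i in seq_len(nParticles)) {
    pos1 <- runif(d, objective@lower, objective@upper)
    pos2 <- runif(d, objective@lower, objective@upper)
    f1 <- evaluateObjective(objective, pos1)
    f2 <- evaluateObjective(objective, pos2)
    if (!is.finite(f1))
      stop(sprintf("non-finite fitness %s for particle %d at position [%s]",
                   format(f1), i, paste(signif(pos1, 4), collapse = ", ")))
    if (!is.finite(f2))
      stop(sprintf("non-finite fitness %s for particle %d at position [%s]",
                   format(f2), i, paste(signif(pos2, 4), collapse = ", ")))
    particles[[i]] <- if (f1 <= f2) newParticle(i, pos1, f1, pos2, f2)
                      else          newParticle(i, pos2, f2, pos1, f1)
  }
  list(particles = particles, global = consolidateGlobalMemory(particles))
}

#' Hierarchical dual-layer memory update
#'
#' Offers a candidate solution to a particle's two-layer memory. A candidate
#' strictly better than the personal best displaces it (the old best drops
#' to the second layer); a candidate at least as good as the best threshold
#' but better than the second layer replaces only the second layer; anything
#' else is discarded. The ordering `fy <= fy2` is preserved, and the two
#' stored values always equal the two smallest fitnesses ever offered.
#'
#' @param particle a particle record (see [initializeSwarm()]).
#' @param candidate numeric position vector.
#' @param candidateFitness its fitness; a non-finite value is discarded with
#'   a warning.
#' @return the updated particle record.
#' @export
updateMemory <- function(particle, candidate, candidateFitness) {
  if (length(candidate) != length(particle$y))
    stop("candidate dimension mismatch")
  if (!is.finite(candidateFitness)) {
    warning(sprintf("discarding non-finite candidate fitness for particle %d",
                    particle$idx))
    return(particle)
  }
  if (candidateFitness < particle$fy) {
    particle$y2 <- particle$y
    particle$fy2 <- particle$fy
    particle$y <- candidate
    particle$fy <- candidateFitness
  } else if (candidateFitness < particle$fy2) {
    particle$y2 <- candidate
    particle$fy2 <- candidateFitness
  }
  particle
}

#' Gaussian candidate generation from a memory pair
#'
#' Bare-bones position sampling: each coordinate is drawn from a normal
#' distribution centered at the midpoint of the two parent positions with
#' standard deviation equal to their absolute coordinate difference, then
#' clipped to the objective's box. Identical parents therefore reproduce
#' themselves exactly (degenerate zero-spread Gaussian).
#'
#' @param p1,p2 parent positions (numeric vectors of equal length).
#' @param objective a [BoxObjective-class] supplying the box.
#' @return a candidate position inside the box.
#' @export
generateCandidate <- function(p1, p2, objective) {
  stopifnot(length(p1) == length(p2))
  x <- rnorm(length(p1), mean = (p1 + p2) / 2, sd = abs(p1 - p2))
  clipToBounds(x, objective)
}

#' Random pairing of particles into leader/worker mini-groups
#'
#' Particle indices are randomly permuted and taken two at a time. Within a
#' pair the particle with the lower personal-best fitness is the leader, the
#' other the worker; ties go to the lower original index. With an odd swarm
#' the leftover particle is returned in `leftover` and is processed in the
#' worker role against the global memory.
#'
#' @param particles list of particle records.
#' @return list with `pairs` (list of `c(leader, worker)` index pairs into
#'   `particles`) and `leftover` (single index or `NULL`).
#' @export
pairParticles <- function(particles) {
  n <- length(particles)
  if (n < 2L) stop("pairing requires at least 2 particles")
  perm <- sample.int(n)
  npair <- n %/% 2L
  pairs <- vector("list", npair)
  for (k in seq_len(npair)) {
    a <- perm[2L * k - 1L]
    b <- perm[2L * k]
    fa <- particles[[a]]$fy
    fb <- particles[[b]]$fy
    lead <- if (fa < fb) a else if (fb < fa) b else min(a, b)
    pairs[[k]] <- c(lead, if (lead == a) b else a)
  }
  leftover <- if (n %% 2L == 1L) perm[n] else NULL
  list(pairs = pairs, leftover = leftover)
}

#' Memory-pair combination lists for a leader/worker pair
#'
#' Builds the four admissible parent pairs for one particle of a mini-group,
#' in canonical order. The leader draws against the global memory:
#' `(gbest, y)`, `(gsecond, y)`, `(gbest, y2)`, `(gsecond, y2)`. The worker
#' draws against the leader's memory: `(y_lead, y)`, `(y2_lead, y)`,
#' `(y_lead, y2)`, `(y2_lead, y2)`.
#'
#' @param role `"leader"` or `"worker"`.
#' @param leader,worker particle records (for `role = "leader"` the `worker`
#'   argument is unused).
#' @param global global memory as returned by [consolidateGlobalMemory()].
#' @return list of 4 `list(p1, p2)` parent pairs.
#' @export
candidateCombinations <- function(role = c("leader", "worker"),
                                  leader, worker = NULL, global) {
  role <- match.arg(role)
  if (role == "leader") {
    list(
      list(p1 = global$gbest, p2 = leader$y),
      list(p1 = global$gsecond, p2 = leader$y),
      list(p1 = global$gbest, p2 = leader$y2),
      list(p1 = global$gsecond, p2 = leader$y2)
    )
  } else {
    list(
      list(p1 = leader$y, p2 = worker$y),
      list(p1 = leader$y2, p2 = worker$y),
      list(p1 = leader$y, p2 = worker$y2),
      list(p1 = leader$y2, p2 = worker$y2)
    )
  }
}

#' Dropout selection of memory-pair combinations
#'
#' Picks 2 of the 4 admissible combinations uniformly without replacement,
#' independently per particle per iteration. This halves the per-iteration
#' evaluation budget (2 instead of 4 candidates per particle) while keeping
#' every combination equally likely.
#'
#' @param combinations list of exactly 4 parent pairs
#'   (see [candidateCombinations()]).
#' @return list of 2 distinct parent pairs.
#' @export
dropoutSelect <- function(combinations) {
  if (length(combinations) != 4L)
    stop("dropout expects exactly 4 combinations")
  combinations[sample.int(4L, 2L)]
}

#' Consolidate all particle memories into the global pool
#'
#' Pools every particle's best and second-best entries (2N in total), sorts
#' by fitness — ties broken by particle index, then by memory layer with the
#' best layer first — and returns the two lowest entries as the global best
#' and global second-best. Both may originate from the same particle.
#'
#' @param particles non-empty list of particle records.
#' @return list with `gbest`, `gbestFitness`, `gsecond`, `gsecondFitness`.
#' @export
consolidateGlobalMemory <- function(particles) {
  n <- length(particles)
  if (n == 0L) stop("cannot consolidate an empty swarm")
  fit <- numeric(2L * n)
  idx <- integer(2L * n)
  layer <- integer(2L * n)
  for (i in seq_len(n)) {
    p <- particles[[i]]
    fit[2L * i - 1L] <- p$fy
    fit[2L * i] <- p$fy2
    idx[c(2L * i - 1L, 2L * i)] <- p$idx
    layer[c(2L * i - 1L, 2L * i)] <- c(1L, 2L)
  }
  ord <- order(fit, idx, layer)
  pick <- function(j) {
    i <- (ord[j] + 1L) %/% 2L
    if (layer[ord[j]] == 1L) particles[[i]]$y else particles[[i]]$y2
  }
  list(gbest = pick(1L), gbestFitness = fit[ord[1L]],
       gsecond = pick(2L), gsecondFitness = fit[ord[2L]])
}

# run one particle's dropout step: build combinations, select 2, generate,
# evaluate, feed both through the memory hierarchy, set x to the better
# candidate. Returns the updated particle.
stepParticle <- function(particle, role, leader, objective, global) {
  combos <- candidateCombinations(role, leader = leader, worker = particle,
                                  global = global)
  chosen <- dropoutSelect(combos)
  bestCand <- NULL
  bestFit <- Inf
  for (cmb in chosen) {
    cand <- generateCandidate(cmb$p1, cmb$p2, objective)
    f <- evaluateObjective(objective, cand)
    particle <- updateMemory(particle, cand, f)
    if (is.finite(f) && f < bestFit) {
      bestFit <- f
      bestCand <- cand
    }
  }
  if (!is.null(bestCand)) particle$x <- bestCand
  particle
}

#' Retrospection dropout bare-bones particle swarm optimization
#'
#' Minimizes a box-bounded objective with a velocity-free swarm. Each
#' particle keeps a dual-layer memory (best and second-best historical
#' solutions). Every iteration the swarm is randomly split into
#' leader/worker pairs; each particle builds its four admissible
#' memory-pair combinations, a dropout step keeps two of them, and two
#' Gaussian candidates are generated and evaluated — exactly
#' `2 * nParticles` evaluations per iteration, half the cost of the
#' exhaustive four-combination variant. After all particles are processed
#' the 2N pooled memories are sorted and their two minima become the global
#' best and second-best for the next iteration.
#'
#' Within a pair the leader is processed first, so the worker draws against
#' the leader's just-updated memories; the global memory is held fixed
#' within an iteration and refreshed at consolidation. With an odd swarm
#' the leftover particle runs the worker combination list with the global
#' best/second-best standing in for the leader's memories.
#'
#' @param objective a [BoxObjective-class] (see [makeObjective()]).
#' @param nParticles swarm size, default 30.
#' @param maxIter number of main-loop iterations, default 100.
#' @param seed integer seed; all stochastic choices (initial draws, pairing
#'   permutation, dropout, Gaussian sampling) consume one seeded stream, so
#'   runs are bit-reproducible.
#' @return a [SwarmTrace-class].
#' @examples
#' sphere <- makeObjective(function(x) sum(x^2), rep(-5, 5), rep(5, 5))
#' tr <- rdbpso(sphere, nParticles = 10, maxIter = 20, seed = 1)
#' tr
#' @export
rdbpso <- function(objective, nParticles = 30L, maxIter = 100L, seed = 1L) {
  stopifnot(is(objective, "BoxObjective"))
  nParticles <- as.integer(nParticles)
  maxIter <- as.integer(maxIter)
  if (nParticles < 2L) stop("'nParticles' must be at least 2")
  if (maxIter < 1L) stop("'maxIter' must be at least 1")
  set.seed(as.integer(seed))

  sw <- initializeSwarm(objective, nParticles)
  particles <- sw$particles
  global <- sw$global

  bestFitness <- numeric(maxIter)
  evals <- integer(maxIter)
  for (t in seq_len(maxIter)) {
    before <- evalCount(objective)
    pp <- pairParticles(particles)
    for (pr in pp$pairs) {
      li <- pr[1L]; wi <- pr[2L]
      particles[[li]] <- stepParticle(particles[[li]], "leader",
                                      leader = particles[[li]],
                                      objective = objective, global = global)
      particles[[wi]] <- stepParticle(particles[[wi]], "worker",
                                      leader = particles[[li]],
                                      objective = objective, global = global)
    }
    if (!is.null(pp$leftover)) {
      ghost <- list(y = global$gbest, fy = global$gbestFitness,
                    y2 = global$gsecond, fy2 = global$gsecondFitness)
      particles[[pp$leftover]] <- stepParticle(particles[[pp$leftover]],
                                               "worker", leader = ghost,
                                               objective = objective,
                                               global = global)
    }
    global <- consolidateGlobalMemory(particles)
    bestFitness[t] <- global$gbestFitness
    evals[t] <- evalCount(objective) - before
  }

  new("SwarmTrace", algorithm = "rdbpso",
      bestFitness = bestFitness, evaluations = evals,
      gbest = global$gbest, gbestFitness = global$gbestFitness,
      gsecond = global$gsecond, gsecondFitness = global$gsecondFitness,
      nEvaluations = evalCount(objective),
      seed = as.integer(seed),
      config = list(nParticles = nParticles, maxIter = maxIter,
                    dim = objective@dim))
}

#' Standard global-best particle swarm optimization
#'
#' Canonical velocity-based PSO baseline with inertia weight `w = 0.7298`
#' and acceleration coefficients `c1 = c2 = 1.49618` (the constriction-
#' equivalent literature values). Velocities are clamped to the box range
#' and positions clipped to the box. One evaluation per particle per
#' iteration.
#'
#' @inheritParams rdbpso
#' @param w,c1,c2 inertia and acceleration coefficients.
#' @return a [SwarmTrace-class] (the `gsecond` slots report the second-best
#'   personal best at termination).
#' @export
standardPso <- function(objective, nParticles = 30L, maxIter = 100L,
                        seed = 1L, w = 0.7298, c1 = 1.49618, c2 = 1.49618) {
  stopifnot(is(objective, "BoxObjective"))
  nParticles <- as.integer(nParticles)
  maxIter <- as.integer(maxIter)
  if (nParticles < 2L) stop("'nParticles' must be at least 2")
  set.seed(as.integer(seed))
  d <- objective@dim
  vmax <- objective@upper - objective@lower

  X <- matrix(runif(nParticles * d, rep(objective@lower, each = nParticles),
                    rep(objective@upper, each = nParticles)),
              nrow = nParticles)
  V <- matrix(0, nParticles, d)
  pbestF <- apply(X, 1L, function(x) evaluateObjective(objective, x))
  if (any(!is.finite(pbestF)))
    stop("non-finite fitness during standard PSO initialization")
  P <- X
  g <- which.min(pbestF)

  bestFitness <- numeric(maxIter)
  evals <- integer(maxIter)
  for (t in seq_len(maxIter)) {
    before <- evalCount(objective)
    for (i in seq_len(nParticles)) {
      r1 <- runif(d); r2 <- runif(d)
      V[i, ] <- w * V[i, ] + c1 * r1 * (P[i, ] - X[i, ]) +
        c2 * r2 * (P[g, ] - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
      X[i, ] <- clipToBounds(X[i, ] + V[i, ], objective)
      f <- evaluateObjective(objective, X[i, ])
      if (is.finite(f) && f < pbestF[i]) {
        pbestF[i] <- f
        P[i, ] <- X[i, ]
        if (f < pbestF[g]) g <- i
      }
    }
    bestFitness[t] <- pbestF[g]
    evals[t] <- evalCount(objective) - before
  }

  ord <- order(pbestF)
  second <- if (nParticles >= 2L) ord[2L] else ord[1L]
  new("SwarmTrace", algorithm = "pso",
      bestFitness = bestFitness, evaluations = evals,
      gbest = P[g, ], gbestFitness = pbestF[g],
      gsecond = P[second, ], gsecondFitness = pbestF[second],
      nEvaluations = evalCount(objective),
      seed = as.integer(seed),
      config = list(nParticles = nParticles, maxIter = maxIter, dim = d,
                    w = w, c1 = c1, c2 = c2))
}

#' Export a swarm trace to JSON or CSV
#'
#' Writes the per-iteration best fitness and evaluation counts together
#' with the seed and configuration echo (JSON), or a plain per-iteration
#' table (CSV) convenient for convergence plots.
#'
#' @param trace a [SwarmTrace-class].
#' @param file output path.
#' @param format `"json"` or `"csv"`.
#' @return `file`, invisibly.
#' @export
exportTrace <- function(trace, file, format = c("json", "csv")) {
  stopifnot(is(trace, "SwarmTrace"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(algorithm = trace@algorithm, seed = trace@seed,
           config = trace@config,
           best_fitness_per_iteration = trace@bestFitness,
           evaluations_per_iteration = trace@evaluations,
           total_evaluations = trace@nEvaluations,
           gbest = trace@gbest, gbest_fitness = trace@gbestFitness,
           gsecond_fitness = trace@gsecondFitness),
      file, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(
      data.frame(iteration = seq_along(trace@bestFitness),
                 best_fitness = trace@bestFitness,
                 evaluations = trace@evaluations),
      file, row.names = FALSE)
  }
  invisible(file)
}
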