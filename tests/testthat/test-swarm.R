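test_that("initialization draws two uniform positions per particle and orders the memory", {
  obj <- sphereObjective(d = 2)
  set.seed(7)
  sw <- initializeSwarm(obj, 30)
  expect_length(sw$particles, 30)
  expect_identical(evalCount(obj), 60L)

  # replay the RNG stream: the recorded memories must be the two draws,
  # ordered by fitness with the first draw winning ties
  set.seed(7)
  for (p in sw$particles) {
    pos1 <- runif(2, -5, 5)
    pos2 <- runif(2, -5, 5)
    f1 <- sum(pos1^2); f2 <- sum(pos2^2)
    if (f1 <= f2) {
      expect_identical(p$y, pos1)
      expect_identical(p$y2, pos2)
    } else {
      expect_identical(p$y, pos2)
      expect_identical(p$y2, pos1)
    }
    expect_lte(p$fy, p$fy2)
    expect_identical(p$x, p$y)
  }
})

test_that("a constant objective resolves the initialization tie toward the first draw", {
  obj <- makeObjective(function(x) 5, 0, 1)
  set.seed(3)
  sw <- initializeSwarm(obj, 5)
  set.seed(3)
  for (p in sw$particles) {
    pos1 <- runif(1, 0, 1); pos2 <- runif(1, 0, 1)
    expect_identical(p$y, pos1)
    expect_identical(p$y2, pos2)
  }
})

test_that("non-finite fitness at initialization aborts with a particle diagnostic", {
  obj <- makeObjective(function(x) NaN, 0, 1)
  set.seed(1)
  expect_error(initializeSwarm(obj, 3), "particle 1")
})

test_that("memory updates follow the three-case hierarchy", {
  p <- particleWith(2, 4)
  up <- updateMemory(p, c(-1), 1)        # better than best
  expect_equal(c(up$fy, up$fy2), c(1, 2))
  expect_equal(up$y2, p$y)               # old best drops one layer

  up <- updateMemory(p, c(9), 3)         # between the layers
  expect_equal(c(up$fy, up$fy2), c(2, 3))

  up <- updateMemory(p, c(9), 2)         # equal to best: second layer only
  expect_equal(c(up$fy, up$fy2), c(2, 2))
  expect_equal(up$y, p$y)

  up <- updateMemory(p, c(9), 9)         # worse than both: discarded
  expect_identical(up[c("fy", "fy2")], p[c("fy", "fy2")])

  expect_warning(up <- updateMemory(p, c(9), NaN), "non-finite")
  expect_identical(up[c("fy", "fy2")], p[c("fy", "fy2")])
})

test_that("the dual-layer memory always holds the two smallest fitnesses ever offered", {
  set.seed(11)
  for (rep in 1:30) {
    f0 <- sort(runif(2, 0, 10))
    p <- particleWith(f0[1], f0[2])
    offered <- f0
    for (cand in runif(40, 0, 10)) {
      p <- updateMemory(p, cand, cand)
      offered <- c(offered, cand)
      expect_lte(p$fy, p$fy2)
    }
    expect_equal(c(p$fy, p$fy2), sort(offered)[1:2])
  }
})

test_that("Gaussian candidates match the midpoint/spread law and respect zero spread", {
  obj <- makeObjective(function(x) 0, rep(-100, 2), rep(100, 2))
  v <- c(1.5, -2)
  set.seed(1)
  expect_identical(generateCandidate(v, v, obj), v)

  # degenerate coordinate stays exact even when the other varies
  draws <- replicate(50, generateCandidate(c(0, 5), c(2, 5), obj))
  expect_true(all(draws[2, ] == 5))

  # Monte-Carlo moment check: mean (p1+p2)/2, sd |p1-p2|, within 4 SE
  n <- 1e5
  set.seed(42)
  X <- t(replicate(n, generateCandidate(c(0, 0), c(2, 4), obj)))
  for (j in 1:2) {
    mu <- c(1, 2)[j]; sig <- c(2, 4)[j]
    expect_lt(abs(mean(X[, j]) - mu), 4 * sig / sqrt(n))
    seSd <- sig / sqrt(2 * (n - 1))
    expect_lt(abs(sd(X[, j]) - sig), 4 * seSd)
  }
})

test_that("candidates are clipped to the objective box", {
  obj <- makeObjective(function(x) 0, 0, 1)
  set.seed(2)
  draws <- replicate(500, generateCandidate(0, 1, obj))
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("pairing partitions the swarm and gives leadership to the better memory", {
  ps <- lapply(1:30, function(i) particleWith(fy = 31 - i, fy2 = 100,
                                              idx = i))
  set.seed(5)
  pp <- pairParticles(ps)
  expect_length(pp$pairs, 15)
  expect_null(pp$leftover)
  all_idx <- unlist(pp$pairs)
  expect_setequal(all_idx, 1:30)
  expect_length(all_idx, 30)
  for (pr in pp$pairs) {
    expect_lte(ps[[pr[1]]]$fy, ps[[pr[2]]]$fy)
  }

  # equal fitness: lower original index leads
  tied <- list(particleWith(1, 2, idx = 1L), particleWith(1, 2, idx = 2L))
  set.seed(1)
  expect_identical(pairParticles(tied)$pairs[[1]], c(1L, 2L))

  expect_error(pairParticles(list(particleWith(1, 2))), "at least 2")
})

test_that("odd swarms leave exactly one leftover worker", {
  ps <- lapply(1:7, function(i) particleWith(i, i + 10, idx = i))
  set.seed(9)
  pp <- pairParticles(ps)
  expect_length(pp$pairs, 3)
  expect_length(pp$leftover, 1)
  expect_setequal(c(unlist(pp$pairs), pp$leftover), 1:7)
})

test_that("combination lists have the canonical four pairs per role", {
  lead <- particleWith(1, 2, d = 3)
  work <- particleWith(5, 6, idx = 2L, d = 3)
  glob <- list(gbest = rep(-1, 3), gbestFitness = 0,
               gsecond = rep(-2, 3), gsecondFitness = 0.5)

  lc <- candidateCombinations("leader", leader = lead, global = glob)
  expect_length(lc, 4)
  for (cmb in lc) {
    fromGlobal <- identical(cmb$p1, glob$gbest) ||
      identical(cmb$p1, glob$gsecond)
    fromLeader <- identical(cmb$p2, lead$y) || identical(cmb$p2, lead$y2)
    expect_true(fromGlobal && fromLeader)
  }
  expect_identical(lc[[1]]$p1, glob$gbest)
  expect_identical(lc[[2]]$p1, glob$gsecond)
  expect_identical(lc[[3]]$p2, lead$y2)

  wc <- candidateCombinations("worker", leader = lead, worker = work,
                              global = glob)
  expect_length(wc, 4)
  for (cmb in wc) {
    fromLeader <- identical(cmb$p1, lead$y) || identical(cmb$p1, lead$y2)
    fromWorker <- identical(cmb$p2, work$y) || identical(cmb$p2, work$y2)
    expect_true(fromLeader && fromWorker)
  }
  # 8 distinct combinations across the two roles
  expect_length(unique(lapply(c(lc, wc), function(x) c(x$p1, x$p2))), 8)
})

test_that("dropout keeps 2 of 4 combinations, uniformly", {
  combos <- lapply(1:4, function(i) list(p1 = i, p2 = i))
  set.seed(13)
  counts <- integer(4)
  for (r in 1:10000) {
    sel <- dropoutSelect(combos)
    expect_length(sel, 2)
    ids <- vapply(sel, function(x) x$p1, numeric(1))
    expect_length(unique(ids), 2)
    counts[ids] <- counts[ids] + 1L
  }
  # each combination selected with probability 1/2
  expect_true(all(abs(counts / 10000 - 0.5) < 0.02))
  expect_error(dropoutSelect(combos[1:3]), "exactly 4")
})

test_that("global consolidation returns the two pooled minima", {
  ps <- list(particleWith(3, 5, idx = 1L), particleWith(1, 4, idx = 2L))
  g <- consolidateGlobalMemory(ps)
  expect_equal(c(g$gbestFitness, g$gsecondFitness), c(1, 3))

  one <- consolidateGlobalMemory(list(particleWith(2, 7)))
  expect_equal(c(one$gbestFitness, one$gsecondFitness), c(2, 7))
  # both entries may come from the same particle
  expect_identical(one$gbest, rep(2, 1))
  expect_identical(one$gsecond, rep(7, 1))

  expect_error(consolidateGlobalMemory(list()), "empty")

  # fuzz against a plain sort over the pooled fitness values
  set.seed(17)
  for (r in 1:20) {
    n <- sample(2:9, 1)
    ps <- lapply(seq_len(n), function(i) {
      f <- sort(runif(2)); particleWith(f[1], f[2], idx = i)
    })
    g <- consolidateGlobalMemory(ps)
    pool <- sort(unlist(lapply(ps, function(p) c(p$fy, p$fy2))))
    expect_equal(c(g$gbestFitness, g$gsecondFitness), pool[1:2])
  }
})

test_that("the optimizer is elitist, budgeted and bit-reproducible", {
  obj <- sphereObjective()
  tr <- rdbpso(obj, nParticles = 30, maxIter = 40, seed = 123)
  expect_true(all(diff(tr@bestFitness) <= 0))
  expect_true(all(tr@evaluations == 60L))
  expect_identical(tr@nEvaluations, 60L + 40L * 60L)
  expect_lte(tr@bestFitness[40], tr@bestFitness[1])
  expect_lte(tr@gbestFitness, tr@gsecondFitness)

  tr2 <- rdbpso(sphereObjective(), nParticles = 30, maxIter = 40,
                seed = 123)
  expect_identical(tr@bestFitness, tr2@bestFitness)
  expect_identical(tr@gbest, tr2@gbest)
})

test_that("odd swarms still consume exactly 2 evaluations per particle per iteration", {
  obj <- sphereObjective(d = 3)
  tr <- rdbpso(obj, nParticles = 5, maxIter = 10, seed = 2)
  expect_true(all(tr@evaluations == 10L))
})

test_that("with dropout disabled the memory end-state matches a two-best brute force", {
  # feed one particle the exact candidate stream of the exhaustive
  # four-combination variant: the dual-layer memory must end up holding
  # the two smallest fitness values ever generated
  obj <- sphereObjective(d = 2)
  set.seed(31)
  sw <- initializeSwarm(obj, 4)
  p <- sw$particles[[1]]
  glob <- sw$global
  seen <- c(p$fy, p$fy2)
  for (t in 1:20) {
    combos <- candidateCombinations("leader", leader = p, global = glob)
    for (cmb in combos) {            # all 4: dropout replaced by take-all
      cand <- generateCandidate(cmb$p1, cmb$p2, obj)
      f <- evaluateObjective(obj, cand)
      p <- updateMemory(p, cand, f)
      seen <- c(seen, f)
    }
  }
  expect_equal(c(p$fy, p$fy2), sort(seen)[1:2])
})

test_that("standard PSO improves convex objectives and honors degenerate boxes", {
  ok <- 0L
  for (s in 1:20) {
    obj <- sphereObjective()
    tr <- standardPso(obj, nParticles = 20, maxIter = 50, seed = s)
    if (tr@bestFitness[50] < tr@bestFitness[1]) ok <- ok + 1L
    expect_true(all(tr@evaluations == 20L))
  }
  expect_gte(ok, 19L)

  # zero-width box: every position identical, fitness constant
  flat <- makeObjective(function(x) sum(x), rep(2, 3), rep(2, 3))
  tr <- standardPso(flat, nParticles = 5, maxIter = 10, seed = 1)
  expect_true(all(tr@bestFitness == 6))
  expect_identical(tr@gbest, rep(2, 3))

  tr2 <- standardPso(makeObjective(function(x) sum(x^2), -5, 5),
                     nParticles = 10, maxIter = 20, seed = 77)
  tr3 <- standardPso(makeObjective(function(x) sum(x^2), -5, 5),
                     nParticles = 10, maxIter = 20, seed = 77)
  expect_identical(tr2@bestFitness, tr3@bestFitness)
})

test_that("sphere optimization contracts the initial best by orders of magnitude", {
  finals <- vapply(1:20, function(s) {
    tr <- rdbpso(sphereObjective(), nParticles = 30, maxIter = 100,
                 seed = s)
    tr@bestFitness[100] / tr@bestFitness[1]
  }, numeric(1))
  expect_lt(median(finals), 1e-2)
})

test_that("trace export round-trips through JSON and CSV", {
  tr <- rdbpso(sphereObjective(d = 2), nParticles = 4, maxIter = 5,
               seed = 1)
  jf <- tempfile(fileext = ".json")
  exportTrace(tr, jf, "json")
  obj <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(obj$best_fitness_per_iteration, tr@bestFitness)
  expect_equal(obj$seed, 1)
  cf <- tempfile(fileext = ".csv")
  exportTrace(tr, cf, "csv")
  df <- read.csv(cf)
  expect_equal(df$best_fitness, tr@bestFitness)
  expect_equal(df$evaluations, tr@evaluations)
})
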