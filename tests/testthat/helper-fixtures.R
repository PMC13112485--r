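# shared fixtures built in code

sphereObjective <- function(d = 5, lo = -5, hi = 5) {
  makeObjective(function(x) sum(x^2), rep(lo, d), rep(hi, d))
}

# a particle record with given memory fitness values (1-D positions carry
# the fitness value itself so positions are easy to identify in tests)
particleWith <- function(fy, fy2, idx = 1L, d = 1L) {
  list(idx = idx, y = rep(fy, d), fy = fy, y2 = rep(fy2, d), fy2 = fy2,
       x = rep(fy, d))
}

# the four confusion matrices printed for the 800-image study, stored as
# clusters x classes counts
printedMatrices <- function() {
  path <- system.file("extdata", "confusion_matrices.csv",
                      package = "rdbpso")
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$algorithm), function(sub) {
    m <- as.matrix(sub[, c("healthy", "tumor")])
    rownames(m) <- sub$cluster
    m
  })
  out
}

# brute-force pair-counting oracle: classify every item pair as together /
# apart in each partition and build ARI and FMI from the 2x2 pair table
pairOracle <- function(clusters, classes) {
  n <- length(clusters)
  ss <- 0; sd_ <- 0; ds <- 0; dd <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      sameC <- clusters[i] == clusters[j]
      sameL <- classes[i] == classes[j]
      if (sameC && sameL) ss <- ss + 1
      else if (sameC && !sameL) sd_ <- sd_ + 1
      else if (!sameC && sameL) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  npairs <- choose(n, 2)
  T <- ss; A <- ss + sd_; B <- ss + ds
  expT <- A * B / npairs
  den <- (A + B) / 2 - expT
  ari <- if (den == 0) {
    if (T == A && A == B) 1 else 0
  } else (T - expT) / den
  fmi <- if (A == 0 || B == 0) 0 else T / sqrt(A * B)
  list(ari = ari, fmi = fmi)
}
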