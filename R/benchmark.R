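#' @importFrom mclust Mclust mclustBIC
NULL

#' Benchmark clustering algorithms on a labeled feature table
#'
#' Runs the requested algorithms repeatedly on the same standardized
#' feature table and scores every run with the five external validation
#' metrics. The swarm methods (`"rdbpso"`, `"standard_pso"`) are fitted
#' through [fitPurityModel()]; the baselines delegate to established
#' implementations — [stats::kmeans()], a full-covariance Gaussian mixture
#' via \pkg{mclust}, and agglomerative clustering via [stats::hclust()]
#' (Ward linkage by default) — all asked for k = 2 clusters. Runs are
#' paired: run r of every algorithm uses `seeds[r]`.
#'
#' @param table labeled feature table (see [simulateFeatureTable()] or
#'   [extractFeatureTable()]).
#' @param algorithms subset of `c("rdbpso", "standard_pso", "kmeans",
#'   "gmm", "hierarchical")`.
#' @param nRuns number of paired runs (default 10).
#' @param seeds integer vector of length `nRuns` (default `1:nRuns`).
#' @param nParticles,maxIter swarm settings (defaults 30 / 100).
#' @param linkage hierarchical linkage criterion (default `"ward.D2"`).
#' @param gmmModel \pkg{mclust} covariance model (default `"VVV"`, full
#'   covariance).
#' @param k number of clusters (default 2).
#' @return data frame with one row per algorithm per run (columns
#'   `algorithm`, `run`, `seed`, the five metrics); convergence traces of
#'   the swarm runs are attached as `attr(, "traces")`, a list keyed by
#'   `"<algorithm>_<run>"`.
#' @export
runBenchmark <- function(table,
                         algorithms = c("rdbpso", "standard_pso", "kmeans",
                                        "gmm", "hierarchical"),
                         nRuns = 10L, seeds = NULL,
                         nParticles = 30L, maxIter = 100L,
                         linkage = "ward.D2", gmmModel = "VVV", k = 2L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (is.null(table$label)) stop("'table' must have a 'label' column")
  nRuns <- as.integer(nRuns)
  if (is.null(seeds)) seeds <- seq_len(nRuns)
  if (length(seeds) != nRuns)
    stop("'seeds' must have length 'nRuns'")

  std <- fitStandardizer(table)
  Z <- featureMatrix(applyStandardizer(std, table))
  labels <- table$label
  hcl <- NULL  # hierarchical clustering is deterministic; computed once

  rows <- list()
  traces <- list()
  for (alg in algorithms) {
    for (r in seq_len(nRuns)) {
      seed <- as.integer(seeds[r])
      cl <- switch(alg,
        rdbpso = {
          fit <- fitPurityModel(table, k = k, algorithm = "rdbpso",
                                nParticles = nParticles, maxIter = maxIter,
                                seed = seed)
          traces[[paste0(alg, "_", r)]] <- fit@trace
          predict(fit, table, what = "cluster")
        },
        standard_pso = {
          fit <- fitPurityModel(table, k = k, algorithm = "pso",
                                nParticles = nParticles, maxIter = maxIter,
                                seed = seed)
          traces[[paste0(alg, "_", r)]] <- fit@trace
          predict(fit, table, what = "cluster")
        },
        kmeans = {
          set.seed(seed)
          stats::kmeans(Z, centers = k, nstart = 1L)$cluster
        },
        gmm = {
          set.seed(seed)
          fit <- Mclust(Z, G = k, modelNames = gmmModel, verbose = FALSE)
          if (is.null(fit)) stop("Gaussian mixture fit failed")
          fit$classification
        },
        hierarchical = {
          if (is.null(hcl))
            hcl <- stats::cutree(stats::hclust(stats::dist(Z),
                                               method = linkage), k = k)
          hcl
        })
      met <- evaluateClustering(cl, labels)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, run = r, seed = seed, t(met))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "traces") <- traces
  out
}

#' Mean/STD stability summary of a benchmark report
#'
#' Aggregates a [runBenchmark()] report into one row per algorithm with the
#' mean and sample (n - 1) standard deviation of each metric over runs, the
#' shape used for multi-run stability comparisons.
#'
#' @param report data frame from [runBenchmark()] (at least 2 runs per
#'   algorithm).
#' @return data frame with columns `algorithm`, then `<metric>_mean` and
#'   `<metric>_sd` for each of the five metrics.
#' @export
stabilitySummary <- function(report) {
  metrics <- c("accuracy", "ari", "nmi", "fmi", "purity")
  stopifnot(all(metrics %in% names(report)))
  algs <- unique(report$algorithm)
  rows <- lapply(algs, function(a) {
    sub <- report[report$algorithm == a, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("stability summary requires at least 2 runs per algorithm")
    vals <- unlist(lapply(metrics, function(m)
      stats::setNames(c(mean(sub[[m]]), stats::sd(sub[[m]])),
                      paste0(m, c("_mean", "_sd")))))
    data.frame(algorithm = a, t(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot per-run metric distributions as box plots
#'
#' Convenience export of the stability comparison: box plots of a chosen
#' metric across runs, one box per algorithm. Requires \pkg{ggplot2}.
#'
#' @param report data frame from [runBenchmark()].
#' @param metric which metric column to plot (default `"purity"`).
#' @return a ggplot object.
#' @export
plotStability <- function(report, metric = "purity") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotStability requires the ggplot2 package")
  stopifnot(metric %in% names(report))
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data[["algorithm"]],
                               y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric)
}

#' Plot convergence traces of swarm runs
#'
#' Per-iteration global best fitness for each stored swarm trace of a
#' benchmark report (or any named list of [SwarmTrace-class] objects).
#' Requires \pkg{ggplot2}.
#'
#' @param traces named list of traces, e.g. `attr(report, "traces")`.
#' @return a ggplot object.
#' @export
plotConvergence <- function(traces) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotConvergence requires the ggplot2 package")
  if (is.data.frame(traces)) traces <- attr(traces, "traces")
  df <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    data.frame(run = nm, algorithm = tr@algorithm,
               iteration = seq_along(tr@bestFitness),
               best_fitness = tr@bestFitness)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["iteration"]],
                                   y = .data[["best_fitness"]],
                                   group = .data[["run"]],
                                   colour = .data[["algorithm"]])) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "iteration", y = "global best fitness")
}
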