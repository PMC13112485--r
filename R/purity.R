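#' Nearest-center assignment
#'
#' Assigns each row of a feature matrix to the Euclidean-nearest cluster
#' center; ties go to the lowest cluster index.
#'
#' @param X numeric matrix (n rows, d feature columns) or data frame.
#' @param centers k-by-d numeric matrix.
#' @return integer vector of cluster indices in `1..k`.
#' @export
assignToCenters <- function(X, centers) {
  X <- featureMatrix(X)
  if (ncol(X) != ncol(centers))
    stop("feature dimension ", ncol(X), " does not match centers (",
         ncol(centers), ")")
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

# decode a flat k*d solution vector into a k-by-d center matrix (row-major:
# the first d entries are center 1)
decodeCenters <- function(solution, k, d) {
  matrix(solution, nrow = k, ncol = d, byrow = TRUE)
}

#' Purity objective for encoded cluster centers
#'
#' Decodes a flat `k * d` solution vector into k centers (row-major),
#' assigns every labeled row to its nearest center, and scores the
#' clustering by purity: the sum over clusters of the majority-class count,
#' divided by n (an empty cluster contributes 0). Returns `1 - purity` so
#' the swarm optimizers, which minimize, maximize purity.
#'
#' @param solution numeric vector of length `k * ncol(X)`.
#' @param X standardized feature matrix or data frame (label column
#'   ignored).
#' @param labels class label per row.
#' @param k number of clusters.
#' @return scalar in `[0, 1 - max class fraction... 1]`, i.e. `1 - purity`.
#' @export
purityFitness <- function(solution, X, labels, k = 2L) {
  X <- featureMatrix(X)
  stopifnot(length(labels) == nrow(X),
            length(solution) == k * ncol(X))
  cl <- assignToCenters(X, decodeCenters(solution, k, ncol(X)))
  tab <- clusterContingency(cl, labels)
  1 - purityScore(tab)
}

#' Fit cluster centers by swarm-optimized purity
#'
#' The full classification fit: standardizes the labeled feature table,
#' encodes k cluster centers as one flat `k * d` vector (canonically
#' `2 * 16 = 32`), and runs a swarm optimizer over the box given by the
#' observed per-dimension minima and maxima of the standardized features,
#' minimizing `1 - purity`. The best solution is decoded and each cluster
#' is mapped to its majority training class (ties and empty clusters map to
#' the first class level, the conservative screening default). The whole
#' table is used for optimization, without a train/test split; the reported
#' purity is therefore a training-set quantity.
#'
#' @param table data frame with the feature columns and a `label` column
#'   containing exactly two (or more) classes.
#' @param k number of clusters (default 2).
#' @param algorithm `"rdbpso"` (default) or `"pso"`.
#' @param nParticles,maxIter,seed optimizer settings (defaults 30 / 100).
#' @return a [PurityModel-class].
#' @examples
#' tab <- simulateFeatureTable(nPerClass = c(30, 30), separation = 6,
#'                             seed = 1)
#' fit <- fitPurityModel(tab, nParticles = 10, maxIter = 20, seed = 1)
#' trainingPurity(fit)
#' @export
fitPurityModel <- function(table, k = 2L, algorithm = c("rdbpso", "pso"),
                           nParticles = 30L, maxIter = 100L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(table$label)) stop("'table' must have a 'label' column")
  labels <- table$label
  lev <- as.character(sort(unique(labels)))
  if (length(lev) < 2L)
    stop("need at least two classes; purity is trivially 1 on one class")
  k <- as.integer(k)
  if (nrow(table) < k) stop("need at least k rows")

  std <- fitStandardizer(table)
  Z <- featureMatrix(applyStandardizer(std, table))
  d <- ncol(Z)
  lo <- apply(Z, 2L, min)
  hi <- apply(Z, 2L, max)
  # widen degenerate dimensions so the box stays valid
  flat <- hi - lo <= 0
  hi[flat] <- lo[flat] + 1e-8

  labInt <- match(labels, lev)
  objective <- makeObjective(function(sol) purityFitness(sol, Z, labInt, k),
                             lower = rep(lo, times = k),
                             upper = rep(hi, times = k))
  trace <- if (algorithm == "rdbpso")
    rdbpso(objective, nParticles = nParticles, maxIter = maxIter,
           seed = seed)
  else
    standardPso(objective, nParticles = nParticles, maxIter = maxIter,
                seed = seed)

  centers <- decodeCenters(trace@gbest, k, d)
  colnames(centers) <- colnames(Z)
  cl <- assignToCenters(Z, centers)
  map <- integer(k)
  for (j in seq_len(k)) {
    counts <- tabulate(labInt[cl == j], nbins = length(lev))
    # majority class; ties (and empty clusters) fall to the first level
    map[j] <- which.max(counts) - 1L
  }
  new("PurityModel", centers = centers, standardizer = std,
      clusterToClass = map, fitness = trace@gbestFitness, trace = trace,
      levels = lev)
}

#' Predict class labels with a fitted purity model
#'
#' Standardizes new feature rows with the model's stored parameters,
#' assigns each to the nearest optimized center, and maps clusters to
#' class labels via the majority map learned at fit time. Rows are
#' independent, so predictions do not depend on batch order.
#'
#' @param object a [PurityModel-class].
#' @param newdata feature data frame or matrix (a `label` column, if
#'   present, is ignored); list of images or file paths are run through
#'   [extractFeatureTable()] first.
#' @param what `"class"` (default) for mapped labels or `"cluster"` for raw
#'   cluster indices.
#' @param ... unused.
#' @return vector of predicted labels (on the training label scale) or
#'   cluster indices.
#' @export
setMethod("predict", "PurityModel",
  function(object, newdata, what = c("class", "cluster"), ...) {
    what <- match.arg(what)
    if (is.list(newdata) && !is.data.frame(newdata))
      newdata <- extractFeatureTable(newdata)
    if (is.character(newdata))
      newdata <- extractFeatureTable(newdata)
    Z <- featureMatrix(applyStandardizer(object@standardizer, newdata))
    cl <- assignToCenters(Z, object@centers)
    if (what == "cluster") return(cl)
    lab <- object@levels[object@clusterToClass[cl] + 1L]
    if (!anyNA(suppressWarnings(as.numeric(object@levels))))
      lab <- as.numeric(lab)
    lab
  })

#' Save or load a purity model as JSON
#'
#' Persists the centers, standardizer parameters, cluster-to-class map,
#' class levels and run configuration; numbers are written at full
#' precision so a reloaded model predicts identically.
#'
#' @param model a [PurityModel-class].
#' @param file path to a JSON file.
#' @return `readPurityModel` returns the model (with an empty trace);
#'   `writePurityModel` returns `file` invisibly.
#' @export
writePurityModel <- function(model, file) {
  stopifnot(is(model, "PurityModel"))
  jsonlite::write_json(
    list(centers = model@centers,
         center_names = colnames(model@centers),
         standardizer = list(center = model@standardizer@center,
                             scale = model@standardizer@scale),
         cluster_to_class = model@clusterToClass,
         levels = model@levels,
         fitness = model@fitness,
         seed = model@trace@seed,
         config = model@trace@config),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writePurityModel
#' @export
readPurityModel <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  centers <- as.matrix(obj$centers)
  colnames(centers) <- obj$center_names
  emptyTrace <- new("SwarmTrace", algorithm = "rdbpso",
                    bestFitness = numeric(0), evaluations = integer(0),
                    gbest = numeric(0), gbestFitness = obj$fitness,
                    gsecond = numeric(0), gsecondFitness = obj$fitness,
                    nEvaluations = 0L,
                    seed = as.integer(obj$seed %||% 0L),
                    config = as.list(obj$config))
  new("PurityModel", centers = centers,
      standardizer = new("FeatureStandardizer",
                         center = unlist(obj$standardizer$center),
                         scale = unlist(obj$standardizer$scale)),
      clusterToClass = as.integer(obj$cluster_to_class),
      fitness = obj$fitness, trace = emptyTrace,
      levels = as.character(obj$levels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
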