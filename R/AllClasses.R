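#' @import methods
NULL

#' Box-bounded minimization objective with evaluation counting
#'
#' A `BoxObjective` wraps a scalar objective function together with its box
#' constraints and a mutable evaluation counter. All optimizers in this
#' package minimize; wrap a maximization problem by negating its objective.
#'
#' @slot fun function mapping a numeric vector of length `dim` to a scalar.
#' @slot dim problem dimension.
#' @slot lower,upper numeric bound vectors of length `dim`, `lower <= upper`.
#' @slot counter environment holding the running evaluation count (`n`).
#'
#' @seealso [makeObjective()], [evalCount()], [rdbpso()]
#' @export
setClass("BoxObjective",
  representation(
    fun = "function",
    dim = "integer",
    lower = "numeric",
    upper = "numeric",
    counter = "environment"
  )
)

setValidity("BoxObjective", function(object) {
  if (length(object@dim) != 1L || object@dim < 1L)
    return("'dim' must be a single positive integer")
  if (length(object@lower) != object@dim || length(object@upper) != object@dim)
    return("bound vectors must have length 'dim'")
  if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)))
    return("bounds must be finite")
  if (any(object@lower > object@upper))
    return("'lower' must be <= 'upper' coordinate-wise")
  TRUE
})

#' Optimization trace of a swarm run
#'
#' Per-iteration record of a swarm optimization together with the final
#' global memory. `bestFitness` holds the pooled global best fitness after
#' each main-loop iteration and is non-increasing by construction (elitist
#' memories are never discarded). `evaluations` counts the objective
#' evaluations consumed by each iteration; for the retrospection dropout
#' optimizer this is exactly `2 * nParticles` every iteration.
#'
#' @slot algorithm character, `"rdbpso"` or `"pso"`.
#' @slot bestFitness numeric vector, global best fitness per iteration.
#' @slot evaluations integer vector, objective evaluations per iteration.
#' @slot gbest,gsecond numeric vectors, final best and second-best pooled
#'   positions.
#' @slot gbestFitness,gsecondFitness their fitness values.
#' @slot nEvaluations total evaluations including initialization.
#' @slot seed integer seed the run was started from.
#' @slot config list echoing the run configuration.
#'
#' @export
setClass("SwarmTrace",
  representation(
    algorithm = "character",
    bestFitness = "numeric",
    evaluations = "integer",
    gbest = "numeric",
    gbestFitness = "numeric",
    gsecond = "numeric",
    gsecondFitness = "numeric",
    nEvaluations = "integer",
    seed = "integer",
    config = "list"
  )
)

setValidity("SwarmTrace", function(object) {
  if (length(object@bestFitness) != length(object@evaluations))
    return("'bestFitness' and 'evaluations' must have equal length")
  if (length(object@gbest) != length(object@gsecond))
    return("'gbest' and 'gsecond' must have equal length")
  if (length(object@gbestFitness) == 1L && length(object@gsecondFitness) == 1L &&
      object@gbestFitness > object@gsecondFitness)
    return("global best fitness must be <= global second-best fitness")
  TRUE
})

#' Per-feature standardization model
#'
#' Stores per-column location and scale fitted on a feature table so the
#' identical z-transform can be replayed on unseen data. Columns with zero
#' spread on the fitting table are mapped to all zeros rather than dividing
#' by zero.
#'
#' @slot center,scale named numeric vectors (fitted mean and standard
#'   deviation per feature).
#' @export
setClass("FeatureStandardizer",
  representation(center = "numeric", scale = "numeric")
)

setValidity("FeatureStandardizer", function(object) {
  if (length(object@center) != length(object@scale))
    return("'center' and 'scale' must have equal length")
  if (any(object@scale < 0)) return("'scale' entries must be >= 0")
  TRUE
})

#' Purity-optimized cluster model
#'
#' The result of fitting k cluster centers in a standardized feature space
#' by swarm optimization of clustering purity. Holds the decoded center
#' matrix, the standardizer used to build the space, the majority-vote map
#' from cluster index to class label, the achieved objective value
#' (1 - purity), and the full optimization trace.
#'
#' @slot centers k-by-d numeric matrix of cluster centers (standardized
#'   space).
#' @slot standardizer a [FeatureStandardizer-class] replayed at prediction
#'   time.
#' @slot clusterToClass integer vector of length k mapping each cluster to
#'   its majority training class.
#' @slot fitness final objective value, `1 - purity` of the training
#'   assignment.
#' @slot trace the [SwarmTrace-class] of the fitting run.
#' @slot levels the class labels the integer codes refer to.
#' @export
setClass("PurityModel",
  representation(
    centers = "matrix",
    standardizer = "FeatureStandardizer",
    clusterToClass = "integer",
    fitness = "numeric",
    trace = "SwarmTrace",
    levels = "character"
  )
)

setValidity("PurityModel", function(object) {
  if (nrow(object@centers) != length(object@clusterToClass))
    return("one class mapping per cluster center required")
  if (length(object@fitness) != 1L || object@fitness < 0 || object@fitness > 1)
    return("'fitness' must be a single value in [0, 1]")
  TRUE
})

setMethod("show", "BoxObjective", function(object) {
  cat("BoxObjective:", object@dim, "dimensions,",
      evalCount(object), "evaluations consumed\n")
})

setMethod("show", "SwarmTrace", function(object) {
  n <- length(object@bestFitness)
  cat(sprintf("SwarmTrace [%s]: %d iterations, %d evaluations\n",
              object@algorithm, n, object@nEvaluations))
  cat(sprintf("  final gbest fitness: %.6g (gsecond %.6g)\n",
              object@gbestFitness, object@gsecondFitness))
})

setMethod("show", "PurityModel", function(object) {
  cat(sprintf("PurityModel: %d centers in %d-dimensional feature space\n",
              nrow(object@centers), ncol(object@centers)))
  cat(sprintf("  training purity: %.4f\n", 1 - object@fitness))
  cat("  cluster -> class:",
      paste(object@levels[object@clusterToClass + 1L], collapse = ", "), "\n")
})

#' @describeIn BoxObjective-class number of objective evaluations consumed
#'   so far.
#' @param objective a `BoxObjective`.
#' @export
evalCount <- function(objective) {
  stopifnot(is(objective, "BoxObjective"))
  objective@counter$n
}

#' @describeIn BoxObjective-class reset the evaluation counter to zero.
#' @export
resetEvalCount <- function(objective) {
  stopifnot(is(objective, "BoxObjective"))
  objective@counter$n <- 0L
  invisible(objective)
}

#' Accessors for fitted purity models and traces
#'
#' @param object a [PurityModel-class] or [SwarmTrace-class].
#' @return `clusterCenters` returns the k-by-d center matrix;
#'   `trainingPurity` the purity of the final training assignment;
#'   `bestFitnessTrace` the per-iteration global best fitness;
#'   `evaluationsPerIteration` the per-iteration objective evaluation
#'   counts.
#' @name accessors
NULL

#' @rdname accessors
#' @export
clusterCenters <- function(object) {
  stopifnot(is(object, "PurityModel"))
  object@centers
}

#' @rdname accessors
#' @export
trainingPurity <- function(object) {
  stopifnot(is(object, "PurityModel"))
  1 - object@fitness
}

#' @rdname accessors
#' @export
bestFitnessTrace <- function(object) {
  if (is(object, "PurityModel")) object <- object@trace
  stopifnot(is(object, "SwarmTrace"))
  object@bestFitness
}

#' @rdname accessors
#' @export
evaluationsPerIteration <- function(object) {
  if (is(object, "PurityModel")) object <- object@trace
  stopifnot(is(object, "SwarmTrace"))
  object@evaluations
}
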