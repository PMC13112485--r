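#' Build a counted, box-bounded objective
#'
#' Wraps a plain R function into a [BoxObjective-class] that validates its
#' box, tracks every evaluation, and is accepted by [rdbpso()] and
#' [standardPso()]. The counter increments by exactly one per call to
#' [evaluateObjective()], which is how the per-iteration evaluation budget
#' of the optimizers is audited.
#'
#' @param fun function of one numeric vector returning a finite scalar
#'   (smaller is better).
#' @param lower,upper numeric bound vectors (recycled to a common length).
#' @return a [BoxObjective-class].
#' @examples
#' sphere <- makeObjective(function(x) sum(x^2), lower = rep(-5, 5),
#'                         upper = rep(5, 5))
#' evaluateObjective(sphere, rep(1, 5))
#' evalCount(sphere)
#' @export
makeObjective <- function(fun, lower, upper) {
  stopifnot(is.function(fun))
  n <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), n)
  upper <- rep_len(as.numeric(upper), n)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  new("BoxObjective", fun = fun, dim = as.integer(n),
      lower = lower, upper = upper, counter = counter)
}

#' Evaluate a counted objective at a point
#'
#' @param objective a [BoxObjective-class].
#' @param x numeric vector of length `objective@dim`.
#' @return scalar fitness; the objective's counter is incremented as a side
#'   effect.
#' @export
evaluateObjective <- function(objective, x) {
  stopifnot(is(objective, "BoxObjective"))
  if (length(x) != objective@dim)
    stop("point has length ", length(x), " but objective dimension is ",
         objective@dim)
  objective@counter$n <- objective@counter$n + 1L
  as.numeric(objective@fun(x))
}

# coordinate-wise projection onto the objective's box
clipToBounds <- function(x, objective) {
  pmin(pmax(x, objective@lower), objective@upper)
}
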