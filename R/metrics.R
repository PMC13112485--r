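#' Cluster-by-class contingency table
#'
#' Counts matrix with one row per cluster and one column per true class;
#' entry (i, j) is the number of items in cluster i with class j. All
#' external validation metrics in this package are functions of this table.
#'
#' @param clusters vector of cluster labels.
#' @param classes vector of true class labels, same length.
#' @return integer matrix with cluster labels as row names and class labels
#'   as column names.
#' @export
clusterContingency <- function(clusters, classes) {
  if (length(clusters) != length(classes))
    stop("label vectors have different lengths")
  if (length(clusters) == 0L) stop("empty label vectors")
  tab <- table(cluster = clusters, class = classes)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

asCounts <- function(t) {
  m <- as.matrix(t)
  if (any(m < 0) || sum(m) < 1) stop("invalid contingency table")
  m
}

#' Purity of a clustering
#'
#' Sum over clusters of the majority-class count, divided by the total
#' count. Always at least the largest class fraction and at most 1.
#'
#' @param t contingency table (clusters x classes), see
#'   [clusterContingency()].
#' @return scalar in (0, 1].
#' @export
purityScore <- function(t) {
  m <- asCounts(t)
  sum(apply(m, 1L, max)) / sum(m)
}

#' Clustering accuracy (majority overlap)
#'
#' Fraction of items that carry the majority class of their own cluster:
#' the sum over clusters of the largest class count, divided by n. This is
#' algebraically identical to [purityScore()]; both are reported because
#' the two names are conventional for the same quantity in external
#' cluster validation. Note that when two clusters share a majority class
#' this exceeds the accuracy of any one-to-one cluster-to-class
#' assignment.
#'
#' @inheritParams purityScore
#' @return scalar in (0, 1].
#' @export
clusterAccuracy <- function(t) {
  purityScore(t)
}

pairCounts <- function(m) {
  list(T = sum(choose(m, 2)),
       A = sum(choose(rowSums(m), 2)),
       B = sum(choose(colSums(m), 2)),
       n = sum(m))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between the clustering and the
#' true classes, computed from the contingency table in the standard
#' pair-counting form. If the correction denominator is zero (both
#' partitions trivial), the value is defined as 1 when the partitions agree
#' on every pair and 0 otherwise.
#'
#' @inheritParams purityScore
#' @return scalar, at most 1.
#' @export
adjustedRandIndex <- function(t) {
  m <- asCounts(t)
  pc <- pairCounts(m)
  if (pc$n < 2) stop("ARI requires at least 2 items")
  expT <- pc$A * pc$B / choose(pc$n, 2)
  den <- (pc$A + pc$B) / 2 - expT
  if (den == 0) {
    if (pc$T == pc$A && pc$A == pc$B) return(1)
    return(0)
  }
  (pc$T - expT) / den
}

#' Normalized mutual information
#'
#' Mutual information between the cluster and class partitions divided by
#' the arithmetic mean of their entropies (`2 I / (H(C) + H(L))`). Natural
#' logarithms are used; any consistent base gives the same ratio. Two
#' trivial partitions (zero total entropy) are defined to have NMI 1.
#'
#' @inheritParams purityScore
#' @return scalar in [0, 1].
#' @export
normalizedMutualInfo <- function(t) {
  m <- asCounts(t)
  n <- sum(m)
  pij <- m / n
  pi_ <- rowSums(pij)
  pj <- colSums(pij)
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  denom <- H(pi_) + H(pj)
  if (denom == 0) return(1)
  2 * I / denom
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall over co-clustered item
#' pairs: `TP / sqrt((TP + FP) (TP + FN))`, with TP the pairs placed
#' together in both partitions, TP + FP the pairs together in the
#' clustering, and TP + FN the pairs together in the true classes. A zero
#' denominator yields 0.
#'
#' @inheritParams purityScore
#' @return scalar in [0, 1].
#' @export
fowlkesMallows <- function(t) {
  m <- asCounts(t)
  pc <- pairCounts(m)
  if (pc$n < 2) stop("FMI requires at least 2 items")
  if (pc$A == 0 || pc$B == 0) return(0)
  pc$T / sqrt(pc$A * pc$B)
}

#' All external validation metrics at once
#'
#' Builds the contingency table of a predicted clustering against true
#' classes and reports accuracy (optimal one-to-one matching), adjusted
#' Rand index, normalized mutual information, Fowlkes-Mallows index and
#' purity (majority overlap).
#'
#' @param clusters predicted cluster labels, or a precomputed contingency
#'   table (then `classes` is omitted).
#' @param classes true class labels.
#' @return named numeric vector with elements `accuracy`, `ari`, `nmi`,
#'   `fmi`, `purity`.
#' @examples
#' evaluateClustering(c(1, 1, 2, 2), c(0, 0, 1, 1))
#' @export
evaluateClustering <- function(clusters, classes = NULL) {
  t <- if (is.null(classes)) asCounts(clusters)
       else clusterContingency(clusters, classes)
  c(accuracy = clusterAccuracy(t),
    ari = adjustedRandIndex(t),
    nmi = normalizedMutualInfo(t),
    fmi = fowlkesMallows(t),
    purity = purityScore(t))
}
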