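# logical ancestor-set matrix restricted to a mutation-id universe:
# AS[i, m] = TRUE iff mutation m is an ancestor of mutation i (self and
# same-clone mutations included, consistent with the package-wide convention)
.ancestorSetMatrix <- function(tree, universe) {
  A <- ancestorMatrix(tree)
  AS <- t(A == 1L)
  diag(AS) <- TRUE
  idx <- match(universe, mutationIds(tree))
  AS[idx, idx, drop = FALSE] * 1
}

#' CASet and DISC distances between clonal trees
#'
#' CASet is the mean, over unordered mutation pairs, of the Jaccard distance
#' between the pair's common-ancestor sets in the two trees; DISC is the mean,
#' over ordered mutation pairs, of the Jaccard distance between the sets of
#' ancestors of the first mutation not shared with the second
#' (distinctly-inherited sets). Ancestor sets include the mutation itself and
#' its same-clone companions. When the trees' mutation universes differ, the
#' comparison is restricted to the shared set (its size is attached as
#' attribute \code{"sharedMutations"}). Two empty sets are at distance zero.
#'
#' @param t1,t2 [ClonalTree-class] objects with overlapping mutation sets.
#' @param metric \code{"CASet"} or \code{"DISC"}.
#' @return numeric in [0, 1].
#' @export
treeDistance <- function(t1, t2, metric = c("CASet", "DISC")) {
  metric <- match.arg(metric)
  shared <- intersect(mutationIds(t1), mutationIds(t2))
  if (length(shared) < 2L) {
    stop("trees share fewer than two mutations; distance undefined")
  }
  A1 <- .ancestorSetMatrix(t1, shared)
  A2 <- .ancestorSetMatrix(t2, shared)
  N <- length(shared)
  if (metric == "CASet") {
    inter <- tcrossprod(A1 * A2)     # |C1(i,j) ^ C2(i,j)|
    s1 <- tcrossprod(A1)             # |C1(i,j)|
    s2 <- tcrossprod(A2)
    uni <- s1 + s2 - inter
    jd <- ifelse(uni > 0, 1 - inter / uni, 0)
    d <- mean(jd[upper.tri(jd)])
  } else {
    # D(i,j) = anc(i) \ anc(j); ordered pairs
    inter <- (A1 * A2) %*% t((1 - A1) * (1 - A2))
    s1 <- A1 %*% t(1 - A1)
    s2 <- A2 %*% t(1 - A2)
    uni <- s1 + s2 - inter
    jd <- ifelse(uni > 0, 1 - inter / uni, 0)
    diag(jd) <- 0
    d <- sum(jd) / (N * (N - 1))
  }
  attr(d, "sharedMutations") <- N
  d
}

#' Density-weighted distance to a reference tree
#'
#' @param density a normalized [TreeDensity-class].
#' @param truth the reference [ClonalTree-class].
#' @param metric passed to [treeDistance()].
#' @return weighted mean distance (numeric scalar).
#' @export
weightedDistance <- function(density, truth, metric = c("CASet", "DISC")) {
  metric <- match.arg(metric)
  density <- normalizeDensity(density)
  d <- vapply(trees(density), function(t) {
    as.numeric(treeDistance(t, truth, metric))
  }, numeric(1))
  sum(treeWeights(density) * d)
}

#' Weight carried by the density's best tree
#'
#' Returns the weight of the tree closest to the reference; trees tied at the
#' minimal distance (within \code{1e-12}) pool their weights, reported via
#' attribute \code{"ties"}.
#'
#' @inheritParams weightedDistance
#' @return numeric scalar with attributes \code{"distance"} (the minimal
#'   distance) and \code{"ties"} (number of tied trees).
#' @export
bestTreeWeight <- function(density, truth, metric = c("CASet", "DISC")) {
  metric <- match.arg(metric)
  density <- normalizeDensity(density)
  d <- vapply(trees(density), function(t) {
    as.numeric(treeDistance(t, truth, metric))
  }, numeric(1))
  best <- which(d <= min(d) + 1e-12)
  w <- sum(treeWeights(density)[best])
  attr(w, "distance") <- min(d)
  attr(w, "ties") <- length(best)
  w
}
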