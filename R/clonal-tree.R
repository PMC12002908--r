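#' Construct a clonal tree
#'
#' @param parent integer vector; \code{parent[i]} is the parent clone index of
#'   clone \code{i} (1-based), \code{NA} for the root. Exactly one root.
#' @param mutClone integer vector mapping each mutation to the clone it
#'   originates in.
#' @param F numeric matrix (samples x clones) of subtree-sum frequencies in
#'   [0, 1]. Row names are sample identifiers (e.g. \code{"blood"},
#'   \code{"tissue1"}). Entries within \code{1e-6} of the valid range or of a
#'   sum-rule violation are clipped; larger violations are errors.
#' @param cloneIds,mutIds optional identifier vectors; defaults
#'   \code{"c1"..} and \code{"m1"..}.
#'
#' @return A [ClonalTree-class] object.
#' @examples
#' tr <- ClonalTree(parent = c(NA, 1L), mutClone = c(1L, 2L),
#'                  F = matrix(c(0.8, 0.3), 1, 2,
#'                             dimnames = list("blood", NULL)))
#' cloneFractions(tr, "blood")
#' @export
ClonalTree <- function(parent, mutClone, F, cloneIds = NULL, mutIds = NULL) {
  parent <- as.integer(parent)
  mutClone <- as.integer(mutClone)
  n <- length(parent)
  if (is.null(cloneIds)) cloneIds <- paste0("c", seq_len(n))
  if (is.null(mutIds)) mutIds <- paste0("m", seq_along(mutClone))
  F <- as.matrix(F)
  if (is.null(rownames(F))) rownames(F) <- paste0("s", seq_len(nrow(F)))
  colnames(F) <- cloneIds
  # clip tiny numerical excursions; validity rejects anything larger
  F[F < 0 & F > -.SUM_RULE_TOL] <- 0
  F[F > 1 & F < 1 + .SUM_RULE_TOL] <- 1
  new("ClonalTree", parent = parent, cloneIds = as.character(cloneIds),
      mutClone = mutClone, mutIds = as.character(mutIds), F = F)
}

#' Accessors for clonal trees
#'
#' \code{parentMatrix} returns the binary parent->child indicator matrix E;
#' \code{mutationMatrix} the binary clone x mutation assignment matrix M;
#' \code{cloneFrequencies} the samples x clones subtree-sum frequency matrix F.
#'
#' @param x a [ClonalTree-class].
#' @param mutations mutation indices or ids.
#' @param clone a clone index or id.
#' @name ClonalTree-accessors
NULL

#' @rdname ClonalTree-accessors
#' @export
setMethod("nClones", "ClonalTree", function(x) length(x@parent))

#' @rdname ClonalTree-accessors
#' @export
setMethod("nMutations", "ClonalTree", function(x) length(x@mutClone))

#' @rdname ClonalTree-accessors
#' @export
setMethod("nSamples", "ClonalTree", function(x) nrow(x@F))

#' @rdname ClonalTree-accessors
#' @export
setMethod("rootClone", "ClonalTree", function(x) which(is.na(x@parent)))

#' @rdname ClonalTree-accessors
#' @export
setMethod("cloneIds", "ClonalTree", function(x) x@cloneIds)

#' @rdname ClonalTree-accessors
#' @export
setMethod("mutationIds", "ClonalTree", function(x) x@mutIds)

#' @rdname ClonalTree-accessors
#' @export
setMethod("parentMatrix", "ClonalTree", function(x) {
  n <- nClones(x)
  E <- matrix(0L, n, n, dimnames = list(x@cloneIds, x@cloneIds))
  for (i in seq_len(n)) if (!is.na(x@parent[i])) E[x@parent[i], i] <- 1L
  E
})

#' @rdname ClonalTree-accessors
#' @export
setMethod("mutationMatrix", "ClonalTree", function(x) {
  M <- matrix(0L, nClones(x), nMutations(x),
              dimnames = list(x@cloneIds, x@mutIds))
  M[cbind(x@mutClone, seq_len(nMutations(x)))] <- 1L
  M
})

#' @rdname ClonalTree-accessors
#' @export
setMethod("cloneFrequencies", "ClonalTree", function(x) x@F)

#' @rdname ClonalTree-accessors
#' @export
setMethod("cloneOf", "ClonalTree", function(x, mutations) {
  idx <- .resolveMutations(x, mutations)
  x@mutClone[idx]
})

#' @rdname ClonalTree-accessors
#' @export
setMethod("childrenOf", "ClonalTree", function(x, clone) {
  if (is.character(clone)) clone <- match(clone, x@cloneIds)
  which(!is.na(x@parent) & x@parent == clone)
})

.resolveMutations <- function(tree, mutations) {
  if (is.character(mutations)) {
    idx <- match(mutations, tree@mutIds)
    if (anyNA(idx)) {
      stop("unknown mutation id(s): ",
           paste(mutations[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    idx <- as.integer(mutations)
    if (any(idx < 1L | idx > nMutations(tree))) {
      stop("mutation index out of range")
    }
    idx
  }
}

# binary clone-level ancestry: anc[i, j] = 1 iff clone i is a proper ancestor
# of clone j
.cloneAncestry <- function(tree) {
  n <- nClones(tree)
  anc <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    v <- tree@parent[j]
    while (!is.na(v)) {
      anc[v, j] <- 1L
      v <- tree@parent[v]
    }
  }
  anc
}

#' Mutation-level ancestor matrix
#'
#' Lifts clone ancestry to mutations: \code{A[i, j] = 1} iff the clone of
#' mutation \code{i} is a proper ancestor of the clone of mutation \code{j},
#' or the two mutations belong to the same clone (with \code{i != j}). The
#' same-clone convention makes all four pairwise relationships (ancestor,
#' descendant, same clone, branched) recoverable from
#' \code{(A[i,j], A[j,i])}: (1,0), (0,1), (1,1) and (0,0) respectively. The
#' diagonal is zero.
#'
#' @param x a [ClonalTree-class].
#' @return binary integer matrix (mutations x mutations) with mutation ids as
#'   dimnames.
#' @seealso [pairRelationship()], [projectPanel()]
#' @rdname ancestorMatrix
#' @export
setMethod("ancestorMatrix", "ClonalTree", function(x) {
  N <- nMutations(x)
  anc <- .cloneAncestry(x)
  cl <- x@mutClone
  A <- anc[cl, cl, drop = FALSE] + outer(cl, cl, "==")
  A[A > 1L] <- 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  dimnames(A) <- list(x@mutIds, x@mutIds)
  A
})

#' Project an ancestor matrix onto a marker panel
#'
#' Restricts a mutation-level ancestor matrix to the selected markers, in
#' panel order, giving the subtree structure the panel can observe.
#'
#' @param A mutation-level ancestor matrix (see [ancestorMatrix()]).
#' @param panel a [MarkerPanel-class] or an integer/character vector of
#'   mutation indices/ids.
#' @return n x n binary matrix, n the panel size.
#' @export
projectPanel <- function(A, panel) {
  idx <- if (is(panel, "MarkerPanel")) panel@markers else panel
  if (is.character(idx)) {
    idx <- match(idx, rownames(A))
    if (anyNA(idx)) stop("panel id not present in ancestor matrix")
  }
  if (any(idx < 1L | idx > nrow(A))) stop("panel index out of range")
  A[idx, idx, drop = FALSE]
}

#' Exclusive clone fractions
#'
#' Converts subtree-sum frequencies F into exclusive clone fractions
#' \eqn{\bar F_i = F_i - \sum_{j \in children(i)} F_j}: the fraction of cells
#' belonging to clone \code{i} itself rather than to its descendants. Small
#' negative results (within \code{tol}) are clipped to zero; violations beyond
#' \code{tol} raise an error.
#'
#' @param x a [ClonalTree-class].
#' @param sample sample name or row index into the frequency matrix; default
#'   the first row.
#' @param tol absolute tolerance for sum-rule violations.
#' @return numeric vector of length \code{nClones(x)}, named by clone id.
#' @rdname cloneFractions
#' @export
setMethod("cloneFractions", "ClonalTree", function(x, sample = NULL,
                                                   tol = 1e-6) {
  if (is.null(sample)) sample <- 1L
  if (is.character(sample)) {
    s <- match(sample, rownames(x@F))
    if (is.na(s)) stop("unknown sample: ", sample)
  } else s <- as.integer(sample)
  f <- x@F[s, ]
  childSum <- numeric(nClones(x))
  for (i in seq_len(nClones(x))) {
    if (!is.na(x@parent[i])) {
      childSum[x@parent[i]] <- childSum[x@parent[i]] + f[i]
    }
  }
  fb <- f - childSum
  if (any(fb < -tol)) {
    stop("sum rule violated beyond tolerance: clone(s) ",
         paste(x@cloneIds[fb < -tol], collapse = ", "))
  }
  fb[fb < 0] <- 0
  names(fb) <- x@cloneIds
  fb
})

#' Relationship between two mutations on a tree
#'
#' Classifies an (ordered) mutation pair into one of the four lineage
#' relationships that determine how their variant allele frequencies are
#' coupled: \code{"ancestor"} (g1 ancestral to g2, f1 >= f2),
#' \code{"descendant"} (f1 <= f2), \code{"same_clone"} (f1 = f2), or
#' \code{"branched"} (distinct branches, f1 + f2 <= 1).
#'
#' @param x a [ClonalTree-class].
#' @param g1,g2 mutation indices or ids; must differ.
#' @return one of \code{"ancestor"}, \code{"descendant"}, \code{"same_clone"},
#'   \code{"branched"}.
#' @rdname pairRelationship
#' @export
setMethod("pairRelationship", "ClonalTree", function(x, g1, g2) {
  i <- .resolveMutations(x, g1)
  j <- .resolveMutations(x, g2)
  if (i == j) stop("pair relationship undefined for a mutation with itself")
  ci <- x@mutClone[i]; cj <- x@mutClone[j]
  if (ci == cj) return("same_clone")
  anc <- .cloneAncestry(x)
  if (anc[ci, cj] == 1L) return("ancestor")
  if (anc[cj, ci] == 1L) return("descendant")
  "branched"
})

setMethod("show", "ClonalTree", function(object) {
  cat(sprintf("ClonalTree: %d clones, %d mutations, %d sample(s)\n",
              nClones(object), nMutations(object), nSamples(object)))
  p <- object@parent
  lab <- vapply(seq_len(nClones(object)), function(i) {
    nm <- sum(object@mutClone == i)
    sprintf("%s%s [%d mut]", object@cloneIds[i],
            if (is.na(p[i])) " (root)" else paste0(" <- ", object@cloneIds[p[i]]),
            nm)
  }, character(1))
  cat(" ", paste(lab, collapse = "; "), "\n")
  if (nSamples(object) > 0L) {
    cat("  samples:", paste(rownames(object@F), collapse = ", "), "\n")
  }
})
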