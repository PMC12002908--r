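#' @import methods
NULL

#' Clonal tree of tumor subpopulations
#'
#' A rooted tree whose nodes are tumor clones. Each somatic mutation originates
#' at exactly one clone and is inherited by the whole subtree below it. The
#' frequency matrix \code{F} stores, per sample and clone, the subtree-sum
#' frequency of that clone's mutations on the VAF-proxy scale (the frequency
#' at which a mutation originating in the clone is observed, i.e. the summed
#' fraction of all cells in the subtree rooted there).
#'
#' @slot parent integer vector of length \code{nClones}; \code{parent[i]} is
#'   the parent clone of clone \code{i}, \code{NA} for the root.
#' @slot cloneIds character vector of clone identifiers.
#' @slot mutClone integer vector of length \code{nMutations}; the clone each
#'   mutation originates in.
#' @slot mutIds character vector of mutation identifiers.
#' @slot F numeric matrix (samples x clones) of subtree-sum frequencies in
#'   [0, 1], satisfying the sum rule: a clone's frequency is at least the sum
#'   of its children's frequencies in every sample.
#'
#' @seealso [ClonalTree()] for the user-facing constructor,
#'   [ancestorMatrix()], [cloneFractions()], [pairRelationship()]
#' @export
setClass("ClonalTree",
  representation(
    parent   = "integer",
    cloneIds = "character",
    mutClone = "integer",
    mutIds   = "character",
    F        = "matrix"
  )
)

.SUM_RULE_TOL <- 1e-6

.treeStructureErrors <- function(parent) {
  n <- length(parent)
  if (n < 1L) return("tree must have at least one clone")
  nroot <- sum(is.na(parent))
  if (nroot != 1L) return(sprintf("expected exactly one root, found %d", nroot))
  idx <- which(!is.na(parent))
  if (any(parent[idx] < 1L | parent[idx] > n)) {
    return("parent index out of range")
  }
  # cycle check: walk up from every node; must reach the root in <= n steps
  for (i in seq_len(n)) {
    v <- i
    for (step in seq_len(n + 1L)) {
      if (is.na(parent[v])) break
      v <- parent[v]
      if (step > n) return("cycle detected in parent structure")
    }
    if (!is.na(parent[v])) return("cycle detected in parent structure")
  }
  NULL
}

setValidity("ClonalTree", function(object) {
  msgs <- character()
  p <- object@parent
  err <- .treeStructureErrors(p)
  if (!is.null(err)) return(err)
  n <- length(p)
  if (length(object@cloneIds) != n) {
    msgs <- c(msgs, "cloneIds length must equal number of clones")
  }
  if (anyDuplicated(object@cloneIds)) msgs <- c(msgs, "duplicate clone ids")
  N <- length(object@mutClone)
  if (length(object@mutIds) != N) {
    msgs <- c(msgs, "mutIds length must equal number of mutations")
  }
  if (anyDuplicated(object@mutIds)) msgs <- c(msgs, "duplicate mutation ids")
  if (N > 0L && any(object@mutClone < 1L | object@mutClone > n)) {
    msgs <- c(msgs, "mutation assigned to nonexistent clone")
  }
  Fm <- object@F
  if (ncol(Fm) != n) msgs <- c(msgs, "F must have one column per clone")
  if (any(Fm < -.SUM_RULE_TOL) || any(Fm > 1 + .SUM_RULE_TOL)) {
    msgs <- c(msgs, "frequencies must lie in [0, 1]")
  }
  # sum rule: parent frequency >= sum of child frequencies, each sample
  if (nrow(Fm) > 0L && n > 1L) {
    childSum <- matrix(0, nrow(Fm), n)
    for (i in seq_len(n)) {
      if (!is.na(p[i])) childSum[, p[i]] <- childSum[, p[i]] + Fm[, i]
    }
    if (any(Fm < childSum - .SUM_RULE_TOL)) {
      msgs <- c(msgs, "sum rule violated: clone frequency below sum of children")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Weighted collection of candidate clonal trees
#'
#' An empirical density over clonal trees, typically estimated by bootstrapping
#' over sequence reads and inferring one tree per replicate. Weights are kept
#' normalized to sum to one; \code{counts} records the bootstrap multiplicity
#' of each distinct topology.
#'
#' @slot trees list of [ClonalTree-class] objects sharing one mutation universe.
#' @slot counts numeric vector of bootstrap multiplicities.
#' @slot weights numeric vector of normalized tree weights.
#'
#' @seealso [TreeDensity()], [normalizeDensity()], [updateWeights()]
#' @export
setClass("TreeDensity",
  representation(
    trees   = "list",
    counts  = "numeric",
    weights = "numeric"
  )
)

setValidity("TreeDensity", function(object) {
  K <- length(object@trees)
  if (K == 0L) return("density must contain at least one tree")
  if (length(object@counts) != K || length(object@weights) != K) {
    return("counts and weights must have one entry per tree")
  }
  if (any(object@counts < 0) || any(object@weights < 0)) {
    return("counts and weights must be nonnegative")
  }
  if (sum(object@weights) <= 0) return("weights must have positive total mass")
  ids <- sort(object@trees[[1L]]@mutIds)
  for (k in seq_len(K)) {
    if (!is(object@trees[[k]], "ClonalTree")) {
      return("all elements of trees must be ClonalTree objects")
    }
    if (!identical(sort(object@trees[[k]]@mutIds), ids)) {
      return("all trees must share the same mutation universe")
    }
  }
  TRUE
})

#' Ordered panel of selected mutation markers
#'
#' The outcome of marker selection: an ordered set of distinct mutations to be
#' assayed at high precision (e.g. by ddPCR).
#'
#' @slot markers integer vector of distinct mutation indices (1-based, into
#'   the mutation universe of the tree/density the panel was selected on).
#' @slot ids character vector of the corresponding mutation identifiers.
#'
#' @seealso [MarkerPanel()], [selectStructureMarkers()], [selectTrackingMarkers()]
#' @export
setClass("MarkerPanel",
  representation(markers = "integer", ids = "character")
)

setValidity("MarkerPanel", function(object) {
  n <- length(object@markers)
  if (n < 1L) return("panel must contain at least one marker")
  if (anyDuplicated(object@markers)) return("duplicate markers in panel")
  if (any(object@markers < 1L)) return("marker indices must be positive")
  if (length(object@ids) != n) return("ids must match markers in length")
  TRUE
})
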