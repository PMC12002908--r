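#' Construct a tree density
#'
#' Builds a weighted collection of candidate clonal trees. Topologically
#' identical trees (same rooted shape and mutation assignment, irrespective of
#' clone labelling) are merged: their counts accumulate and their frequency
#' matrices are averaged count-weighted, so bootstrap replicates of one
#' topology collapse into a single entry. Weights are initialized proportional
#' to counts and normalized to sum to one.
#'
#' @param trees list of [ClonalTree-class] objects over one mutation universe.
#' @param counts nonnegative multiplicities, default 1 per tree.
#' @param deduplicate merge topologically identical trees (default TRUE).
#' @return A [TreeDensity-class] object.
#' @export
TreeDensity <- function(trees, counts = NULL, deduplicate = TRUE) {
  if (is(trees, "ClonalTree")) trees <- list(trees)
  if (is.null(counts)) counts <- rep(1, length(trees))
  counts <- as.numeric(counts)
  if (length(counts) != length(trees)) {
    stop("counts must have one entry per tree")
  }
  if (deduplicate && length(trees) > 1L) {
    trees <- lapply(trees, .canonicalCloneOrder)
    keys <- vapply(trees, canonicalTreeKey, character(1))
    grp <- match(keys, unique(keys))
    merged <- vector("list", max(grp))
    mcount <- numeric(max(grp))
    for (g in seq_len(max(grp))) {
      sel <- which(grp == g)
      mcount[g] <- sum(counts[sel])
      tr <- trees[[sel[1L]]]
      if (length(sel) > 1L && mcount[g] > 0) {
        Fs <- Reduce(`+`, lapply(sel, function(i) {
          counts[i] * trees[[i]]@F
        })) / mcount[g]
        tr@F <- Fs
      }
      merged[[g]] <- tr
    }
    trees <- merged
    counts <- mcount
  }
  w <- counts
  if (sum(w) <= 0) w <- rep(1, length(trees))
  new("TreeDensity", trees = trees, counts = counts, weights = w / sum(w))
}

#' Canonical key of a clonal tree topology
#'
#' Label-invariant serialization of (tree shape, mutation assignment): each
#' clone is rendered as its sorted mutation-id set with its children's
#' serializations nested and sorted. Two trees get the same key iff they have
#' the same rooted topology with the same mutations at each node.
#'
#' @param tree a [ClonalTree-class].
#' @return character scalar.
#' @export
canonicalTreeKey <- function(tree) {
  kids <- lapply(seq_len(nClones(tree)), function(i) childrenOf(tree, i))
  muts <- split(tree@mutIds, factor(tree@mutClone, levels = seq_len(nClones(tree))))
  ser <- function(i) {
    own <- paste(sort(muts[[i]]), collapse = ",")
    ch <- vapply(kids[[i]], ser, character(1))
    paste0("{", own, "}(", paste(sort(ch), collapse = "|"), ")")
  }
  ser(rootClone(tree))
}

# reorder clones into the canonical DFS order implied by canonicalTreeKey
# (children visited in sorted-serialization order), so topologically identical
# trees end up with identical parent vectors and aligned frequency columns
.canonicalCloneOrder <- function(tree) {
  n <- nClones(tree)
  kids <- lapply(seq_len(n), function(i) childrenOf(tree, i))
  muts <- split(tree@mutIds, factor(tree@mutClone, levels = seq_len(n)))
  serCache <- character(n)
  ser <- function(i) {
    if (nzchar(serCache[i])) return(serCache[i])
    own <- paste(sort(muts[[i]]), collapse = ",")
    ch <- vapply(kids[[i]], ser, character(1))
    serCache[i] <<- paste0("{", own, "}(", paste(sort(ch), collapse = "|"), ")")
    serCache[i]
  }
  order_ <- integer(0)
  visit <- function(i) {
    order_ <<- c(order_, i)
    for (c0 in kids[[i]][order(vapply(kids[[i]], ser, character(1)))]) visit(c0)
  }
  visit(rootClone(tree))
  if (identical(order_, seq_len(n))) return(tree)
  inv <- match(seq_len(n), order_)   # old index -> new position
  newParent <- ifelse(is.na(tree@parent[order_]), NA_integer_,
                      inv[tree@parent[order_]])
  ClonalTree(newParent, inv[tree@mutClone],
             tree@F[, order_, drop = FALSE],
             cloneIds = paste0("c", seq_len(n)), mutIds = tree@mutIds)
}

#' Accessors for tree densities
#'
#' @param x a [TreeDensity-class].
#' @name TreeDensity-accessors
NULL

#' @rdname TreeDensity-accessors
#' @export
setMethod("trees", "TreeDensity", function(x) x@trees)

#' @rdname TreeDensity-accessors
#' @export
setMethod("treeWeights", "TreeDensity", function(x) x@weights)

#' @rdname TreeDensity-accessors
#' @export
setMethod("treeCounts", "TreeDensity", function(x) x@counts)

#' @rdname TreeDensity-accessors
#' @export
setMethod("length", "TreeDensity", function(x) length(x@trees))

#' @rdname TreeDensity-accessors
#' @export
setMethod("[[", "TreeDensity", function(x, i) x@trees[[i]])

#' Normalize tree-density weights
#'
#' Rescales weights to sum to one, preserving proportions. Idempotent.
#'
#' @param x a [TreeDensity-class] with at least one positive weight.
#' @return the normalized [TreeDensity-class].
#' @rdname normalizeDensity
#' @export
setMethod("normalizeDensity", "TreeDensity", function(x) {
  tot <- sum(x@weights)
  if (tot <= 0) stop("degenerate density: all weights are zero")
  x@weights <- x@weights / tot
  x
})

setMethod("show", "TreeDensity", function(object) {
  K <- length(object@trees)
  cat(sprintf("TreeDensity: %d distinct tree(s), %g total bootstrap count\n",
              K, sum(object@counts)))
  ord <- order(object@weights, decreasing = TRUE)
  shown <- head(ord, 5L)
  for (k in shown) {
    cat(sprintf("  tree %d: weight %.3f (count %g), %d clones\n", k,
                object@weights[k], object@counts[k],
                nClones(object@trees[[k]])))
  }
  if (K > 5L) cat(sprintf("  ... and %d more\n", K - 5L))
})

#' Construct a marker panel
#'
#' @param markers integer vector of distinct mutation indices, or character
#'   vector of mutation ids when \code{universe} is given.
#' @param universe optional character vector of mutation ids (e.g.
#'   \code{mutationIds(tree)}) used to resolve/label markers.
#' @return A [MarkerPanel-class].
#' @export
MarkerPanel <- function(markers, universe = NULL) {
  if (is.character(markers)) {
    if (is.null(universe)) stop("character markers require a universe of ids")
    idx <- match(markers, universe)
    if (anyNA(idx)) {
      stop("unknown marker id(s): ", paste(markers[is.na(idx)], collapse = ", "))
    }
    ids <- markers
  } else {
    idx <- as.integer(markers)
    ids <- if (!is.null(universe)) universe[idx] else paste0("m", idx)
  }
  new("MarkerPanel", markers = as.integer(idx), ids = as.character(ids))
}

#' Accessors for marker panels
#'
#' @param x a [MarkerPanel-class].
#' @name MarkerPanel-accessors
NULL

#' @rdname MarkerPanel-accessors
#' @export
setMethod("markerIndices", "MarkerPanel", function(x) x@markers)

#' @rdname MarkerPanel-accessors
#' @export
setMethod("markerIds", "MarkerPanel", function(x) x@ids)

#' @rdname MarkerPanel-accessors
#' @export
setMethod("length", "MarkerPanel", function(x) length(x@markers))

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel: %d marker(s): %s\n", length(object@markers),
              paste(object@ids, collapse = ", ")))
})
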