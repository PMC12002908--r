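# per-tree precomputation for the tracking objective
.trackingContext <- function(tree, weights) {
  n <- nClones(tree)
  w <- if (is.null(weights)) {
    cloneFractions(tree, if ("blood" %in% rownames(tree@F)) "blood" else 1L)
  } else {
    stopifnot(length(weights) == n)
    as.numeric(weights)
  }
  if (any(w < 0)) stop("tracking weights must be nonnegative")
  list(mutClone = tree@mutClone,
       children = lapply(seq_len(n), function(i) childrenOf(tree, i)),
       w = w)
}

# weighted tracked mass of a marker set on one tree
.trackedMass <- function(ctx, markers, mode) {
  covered <- tabulate(ctx$mutClone[markers], nbins = length(ctx$w)) > 0L
  tracked <- if (mode == "partial") {
    covered
  } else {
    vapply(seq_along(ctx$w), function(i) {
      covered[i] && all(covered[ctx$children[[i]]])
    }, logical(1))
  }
  sum(ctx$w[tracked])
}

#' Fraction of clonal mass trackable with a panel
#'
#' Under the partial-information assumption a clone is trackable when some
#' selected marker originates in it (its subtree frequency is then
#' measurable); under the complete-information assumption the clone and all
#' of its children must carry selected markers, so the clone's own exclusive
#' fraction can be isolated by subtraction.
#'
#' @param tree a [ClonalTree-class].
#' @param panel a [MarkerPanel-class] or integer vector of mutation indices
#'   (may be empty, yielding 0).
#' @param mode \code{"partial"} (default) or \code{"complete"}.
#' @param weights per-clone weights; default the exclusive clone fractions of
#'   the blood sample (first sample if no blood row).
#' @return the tracked share of the total weight, in [0, 1].
#' @export
trackableFraction <- function(tree, panel, mode = c("partial", "complete"),
                              weights = NULL) {
  mode <- match.arg(mode)
  idx <- if (is(panel, "MarkerPanel")) panel@markers else as.integer(panel)
  ctx <- .trackingContext(tree, weights)
  tot <- sum(ctx$w)
  if (tot <= 0) stop("total clone-fraction mass is zero; fraction undefined")
  .trackedMass(ctx, idx, mode) / tot
}

#' Select markers maximizing the tracked clonal mass
#'
#' Chooses \code{n} markers maximizing the weighted sum of trackable clones,
#' in expectation over a tree density (a single tree is the one-tree density
#' special case). The objective is the density-weighted tracked mass of
#' [trackableFraction()] (unnormalized), a monotone set function maximized
#' exactly by branch-and-bound with the add-all-remaining upper bound, or by
#' exhaustive enumeration on small instances. Lexicographically smallest panel
#' among ties. Clones without any mutation can never be tracked; with more
#' markers requested than positively weighted clones, surplus markers fall to
#' the lowest available indices.
#'
#' @param density a [TreeDensity-class] or a single [ClonalTree-class].
#' @param n panel size.
#' @param mode \code{"partial"} or \code{"complete"} information assumption.
#' @param weights per-tree clone weights: \code{"fractions"} (default; each
#'   tree's exclusive blood-sample clone fractions, i.e. the previous time
#'   point's estimates in longitudinal use), \code{"uniform"}, or a list of
#'   numeric vectors (one per tree).
#' @param solverMode \code{"auto"}, \code{"exact"}, or \code{"exhaustive"}.
#' @return a [MarkerPanel-class].
#' @export
selectTrackingMarkers <- function(density, n, mode = c("partial", "complete"),
                                  weights = "fractions",
                                  solverMode = c("auto", "exact", "exhaustive")) {
  mode <- match.arg(mode)
  if (is(density, "ClonalTree")) density <- TreeDensity(list(density))
  density <- normalizeDensity(density)
  trs <- trees(density)
  wts <- treeWeights(density)
  K <- length(trs)
  N <- nMutations(trs[[1L]])
  if (n > N) stop("panel size exceeds number of mutations")
  wlist <- if (identical(weights, "fractions")) {
    rep(list(NULL), K)
  } else if (identical(weights, "uniform")) {
    lapply(trs, function(t) rep(1 / nClones(t), nClones(t)))
  } else {
    stopifnot(is.list(weights), length(weights) == K)
    weights
  }
  ctxs <- Map(.trackingContext, trs, wlist)
  # markers are selected on the shared mutation-id universe; map ids to each
  # tree's own mutation order
  ids <- mutationIds(trs[[1L]])
  maps <- lapply(trs, function(t) match(ids, mutationIds(t)))
  scoreFun <- function(S) {
    tot <- 0
    for (k in seq_len(K)) {
      tot <- tot + wts[k] * .trackedMass(ctxs[[k]], maps[[k]][S], mode)
    }
    tot
  }
  mmode <- .resolveSolverMode(solverMode, N, n)
  res <- if (mmode == "exhaustive") {
    .exhaustiveMax(scoreFun, N, n)
  } else {
    prof <- .mutationProfiles(density)
    G <- length(prof$members)
    reps <- vapply(prof$members, `[`, integer(1), 1L)
    # per-tree clone hit by each profile group, and tree-weighted clone masses
    profMat <- do.call(rbind, lapply(seq_len(K), function(k) {
      ctxs[[k]]$mutClone[maps[[k]][reps]]
    }))
    wtsList <- lapply(seq_len(K), function(k) wts[k] * ctxs[[k]]$w)
    childrenList <- lapply(ctxs, `[[`, "children")
    sol <- .trackingGroupSolver(profMat, wtsList, childrenList, n, mode)
    m <- length(sol$groups)
    repsSel <- reps[sol$groups]
    pad <- setdiff(seq_len(N), repsSel)[seq_len(n - m)]
    list(best = sort(c(repsSel, pad)), value = sol$value)
  }
  untrackable <- which(vapply(seq_len(nClones(trs[[1L]])), function(i) {
    sum(trs[[1L]]@mutClone == i) == 0L
  }, logical(1)))
  if (length(untrackable)) {
    message("clone(s) without mutations can never be tracked: ",
            paste(cloneIds(trs[[1L]])[untrackable], collapse = ", "))
  }
  MarkerPanel(res$best, universe = ids)
}
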