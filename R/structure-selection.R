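#' Parameters of the structure-discrimination objective
#'
#' The assay model treats the read count of a marker with latent frequency F
#' at depth D as approximately Gaussian with mean \code{D * F} and variance
#' \code{D * F * (1 - F)}. Topology differences between candidate trees are
#' scored through the ancestor-descendant structure of the selected markers,
#' with a regularization factor \code{lambda >= 1} per unit of
#' ancestor-matrix difference.
#'
#' @param depth assay read depth D (positive).
#' @param lambda structure regularization factor, >= 1. \code{lambda = 1}
#'   switches the structure term off.
#' @param logLambda optional log-scale specification of the regularization
#'   factor, overriding \code{lambda}; useful in the structure-dominant
#'   regime where \code{exp(logLambda)} would overflow.
#' @param sample which frequency row parameterizes the assay model: a sample
#'   name, a row index, or \code{NULL} for the default (the \code{"blood"}
#'   row if present, else the mean over all samples).
#' @param includeConstant include the panel-dependent Gaussian normalization
#'   term \code{0.5 * sum(log(2 * pi * (s2q + s2k)))} in the objective
#'   (default TRUE).
#' @param objectiveSign \code{"discriminative"} (default) scores a panel by
#'   how well it separates candidate trees (read-model divergence plus
#'   structure differences, to be maximized); \code{"literal"} scores by the
#'   cross-tree log-likelihood plus structure term with its printed sign.
#' @param varFloor variance floor as a fraction of depth, guarding
#'   frequencies of exactly 0 or 1.
#' @return a list of class \code{"structureParams"}.
#' @export
structureParams <- function(depth, lambda = 2, sample = NULL,
                            includeConstant = TRUE,
                            objectiveSign = c("discriminative", "literal"),
                            varFloor = 1e-6, logLambda = NULL) {
  stopifnot(depth >= 1, lambda >= 1, varFloor > 0)
  objectiveSign <- match.arg(objectiveSign)
  if (is.null(logLambda)) logLambda <- log(lambda)
  stopifnot(is.finite(logLambda), logLambda >= 0)
  structure(list(depth = depth, lambda = lambda, logLambda = logLambda,
                 sample = sample,
                 includeConstant = includeConstant,
                 objectiveSign = objectiveSign, varFloor = varFloor),
            class = "structureParams")
}

# frequency vector over mutations for the assay model's sample choice
.assayFrequencies <- function(tree, sample) {
  Fm <- cloneFrequencies(tree)
  if (is.null(sample)) {
    row <- if ("blood" %in% rownames(Fm)) {
      Fm["blood", ]
    } else colMeans(Fm)
  } else if (is.character(sample)) {
    if (!sample %in% rownames(Fm)) stop("unknown sample: ", sample)
    row <- Fm[sample, ]
  } else row <- Fm[as.integer(sample), ]
  row[tree@mutClone]
}

#' Gaussian read-count moments for a marker panel
#'
#' @param tree a [ClonalTree-class].
#' @param panel a [MarkerPanel-class] or integer vector of mutation indices.
#' @param params a [structureParams()] list.
#' @return list with numeric vectors \code{mu} and \code{sigma2} (one entry
#'   per panel marker); \code{sigma2} is floored at
#'   \code{varFloor * depth}.
#' @export
gaussianMoments <- function(tree, panel, params) {
  idx <- if (is(panel, "MarkerPanel")) {
    match(panel@ids, mutationIds(tree))  # id-resolved, robust to order
  } else as.integer(panel)
  f <- unname(.assayFrequencies(tree, params$sample)[idx])
  mu <- params$depth * f
  sigma2 <- pmax(params$depth * f * (1 - f), params$varFloor * params$depth)
  list(mu = mu, sigma2 = sigma2)
}

#' Cross-tree divergence contributed by one ordered tree pair
#'
#' The per-ordered-pair term of the structure-selection objective: the
#' expected log-likelihood of reads generated under tree \code{treeK} scored
#' under tree \code{treeQ} (read component), plus the structure component
#' \code{log(lambda)} times the number of differing entries of the two
#' panel-projected ancestor matrices.
#'
#' @param treeQ,treeK [ClonalTree-class] objects over one mutation universe.
#' @param panel a [MarkerPanel-class] or integer vector.
#' @param params a [structureParams()] list.
#' @param components if TRUE return a list with \code{read} and
#'   \code{structure} parts instead of their sum.
#' @return numeric scalar (or a two-component list).
#' @export
pairDivergence <- function(treeQ, treeK, panel, params, components = FALSE) {
  gq <- gaussianMoments(treeQ, panel, params)
  gk <- gaussianMoments(treeK, panel, params)
  v <- gq$sigma2 + gk$sigma2
  readComp <- -0.5 * sum((gk$mu - gq$mu)^2 / v)
  if (params$includeConstant) readComp <- readComp - 0.5 * sum(log(2 * pi * v))
  sel <- if (is(panel, "MarkerPanel")) markerIds(panel) else panel
  Ahq <- projectPanel(ancestorMatrix(treeQ), sel)
  Ahk <- projectPanel(ancestorMatrix(treeK), sel)
  structComp <- params$logLambda * sum(abs(Ahk - Ahq))
  if (components) list(read = readComp, structure = structComp)
  else readComp + structComp
}

# linear (per-marker) and pairwise (per marker pair) coefficients of the
# selection score over the full mutation universe, so that
# score(panel) = sum(cvec[panel]) + sum(Q[panel, panel])
.structureCoefficients <- function(density, params) {
  trs <- trees(density)
  w <- treeWeights(density)
  K <- length(trs)
  ids <- mutationIds(trs[[1L]])
  N <- length(ids)
  # align every tree to the first tree's mutation order
  fmat <- vapply(trs, function(t) {
    unname(.assayFrequencies(t, params$sample)[match(ids, mutationIds(t))])
  }, numeric(N))
  mu <- params$depth * fmat                      # N x K
  s2 <- pmax(params$depth * fmat * (1 - fmat), params$varFloor * params$depth)
  amats <- lapply(trs, function(t) ancestorMatrix(t)[ids, ids, drop = FALSE])
  sgn <- if (params$objectiveSign == "discriminative") 1 else -1
  cvec <- numeric(N)
  Q <- matrix(0, N, N)
  llam <- params$logLambda
  for (q in seq_len(K)) {
    for (k in seq_len(K)) {
      if (k == q) next
      ww <- w[q] * w[k]
      v <- s2[, q] + s2[, k]
      r <- 0.5 * (mu[, k] - mu[, q])^2 / v
      if (params$includeConstant) r <- r + 0.5 * log(2 * pi * v)
      cvec <- cvec + ww * sgn * r
      if (llam > 0) Q <- Q + (ww * llam) * abs(amats[[k]] - amats[[q]])
    }
  }
  list(cvec = cvec, Q = Q, mutIds = mutationIds(trs[[1L]]))
}

#' Structure-discrimination score of a marker panel
#'
#' Scores a panel over a tree density by summing [pairDivergence()] terms over
#' all ordered pairs of distinct trees, weighted by the product of the two
#' trees' weights. Under the default \code{objectiveSign = "discriminative"}
#' the read component enters with flipped sign, so the returned value rewards
#' panels whose expected read counts and projected ancestor structures
#' separate the candidate trees; marker selection maximizes it.
#'
#' @param density a [TreeDensity-class] (at least two distinct trees for the
#'   structure term to be informative; a single tree gives a constant-in-panel
#'   structure term and raises a warning).
#' @param panel a [MarkerPanel-class] or integer vector.
#' @param params a [structureParams()] list.
#' @return numeric scalar.
#' @export
structureObjective <- function(density, panel, params) {
  if (length(density) < 2L) {
    warning("density has a single tree: objective is constant in the structure term")
  }
  idx <- if (is(panel, "MarkerPanel")) panel@markers else as.integer(panel)
  co <- .structureCoefficients(density, params)
  sum(co$cvec[idx]) + sum(co$Q[idx, idx, drop = FALSE])
}

#' Select markers that best discriminate candidate tree structures
#'
#' Chooses the panel of \code{n} markers maximizing [structureObjective()]
#' over the tree density: a linear-plus-pairwise binary program (binary
#' selection variables with linearized pairwise products and a cardinality
#' constraint), solved exactly by branch-and-bound, or by exhaustive
#' enumeration for small instances. Among equal-scoring optima the
#' lexicographically smallest index set is returned.
#'
#' @param density a [TreeDensity-class].
#' @param n panel size.
#' @param params a [structureParams()] list.
#' @param solverMode \code{"auto"} (default; exhaustive for small instances,
#'   branch-and-bound otherwise), \code{"exact"}, or \code{"exhaustive"}.
#' @return a [MarkerPanel-class].
#' @export
selectStructureMarkers <- function(density, n, params,
                                   solverMode = c("auto", "exact", "exhaustive")) {
  density <- normalizeDensity(density)
  co <- .structureCoefficients(density, params)
  N <- length(co$cvec)
  if (n > N) stop("panel size exceeds number of mutations")
  mode <- .resolveSolverMode(solverMode, N, n)
  res <- if (mode == "exhaustive") {
    .exhaustiveMax(function(S) sum(co$cvec[S]) + sum(co$Q[S, S, drop = FALSE]),
                   N, n)
  } else {
    prof <- .mutationProfiles(density)
    reps <- vapply(prof$members, `[`, integer(1), 1L)
    grouped <- .solveGroupedPairwise(co$cvec[reps],
                                     co$Q[reps, reps, drop = FALSE],
                                     prof$members, n)
    if (is.null(grouped)) .solvePairwiseMax(co$cvec, co$Q, n) else grouped
  }
  MarkerPanel(res$best, universe = co$mutIds)
}
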