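#' Log marginal likelihood of a marker pair's read counts given a relationship
#'
#' For two markers assayed at high precision (binomial read counts
#' \code{r ~ Bin(d, f)}), the lineage relationship between the markers
#' constrains their latent frequencies: ancestor (\code{f1 >= f2}),
#' descendant (\code{f1 <= f2}), same clone (\code{f1 = f2}), or branched
#' (\code{f1 + f2 <= 1}). This computes the log of the marginal likelihood of
#' the observed counts with the frequencies integrated uniformly over the
#' corresponding region, binomial coefficients included (they are constant
#' across trees for fixed counts and cancel on normalization).
#'
#' The ordered-region and anti-diagonal cases reduce to one-dimensional
#' integrals of a beta density times a regularized incomplete beta function,
#' evaluated by adaptive quadrature (relative tolerance \code{relTol}) with a
#' panelled Gauss-Legendre log-space fallback for extreme counts; the
#' same-clone case has the closed form \code{Beta(r1+r2+1, d1+d2-r1-r2+1)}.
#'
#' @param relationship one of \code{"ancestor"}, \code{"descendant"},
#'   \code{"same_clone"}, \code{"branched"}.
#' @param r1,d1 variant reads and depth of marker 1 (0 <= r1 <= d1).
#' @param r2,d2 variant reads and depth of marker 2.
#' @param relTol relative tolerance of the quadrature.
#' @return log-likelihood (numeric scalar, finite for valid counts).
#' @export
pairIntegralLog <- function(relationship, r1, d1, r2, d2, relTol = 1e-8) {
  relationship <- match.arg(relationship,
                            c("ancestor", "descendant", "same_clone", "branched"))
  stopifnot(r1 >= 0, r2 >= 0, d1 >= 0, d2 >= 0)
  if (r1 > d1 || r2 > d2) stop("variant reads exceed depth")
  lc <- lchoose(d1, r1) + lchoose(d2, r2)
  if (relationship == "same_clone") {
    return(lc + lbeta(r1 + r2 + 1, d1 + d2 - r1 - r2 + 1))
  }
  if (relationship == "descendant") {
    # f1 <= f2 is the ancestor case with the markers swapped
    tmp <- r1; r1 <- r2; r2 <- tmp
    tmp <- d1; d1 <- d2; d2 <- tmp
    relationship <- "ancestor"
  }
  # ancestor: int_0^1 f1^r1 (1-f1)^(d1-r1) * int_0^f1 f2^r2 (1-f2)^(d2-r2)
  # branched: inner integral runs over f2 in [0, 1-f1]
  a1 <- r1 + 1; b1 <- d1 - r1 + 1
  a2 <- r2 + 1; b2 <- d2 - r2 + 1
  inner <- function(f) {
    u <- if (relationship == "ancestor") f else 1 - f
    stats::pbeta(u, a2, b2)
  }
  val <- tryCatch({
    stats::integrate(function(f) stats::dbeta(f, a1, b1) * inner(f),
                     0, 1, rel.tol = relTol, subdivisions = 500L)$value
  }, error = function(e) NA_real_)
  logInner <- if (is.finite(val) && val > 1e-280) {
    log(val)
  } else {
    .logInnerIntegralGL(a1, b1, a2, b2, relationship)
  }
  lc + lbeta(a1, b1) + lbeta(a2, b2) + logInner
}

# log of int_0^1 dbeta(f; a1, b1) * pbeta(u(f); a2, b2) df computed in log
# space on Gauss-Legendre panels concentrated around the beta peak, for counts
# so extreme that the linear-scale integral underflows
.logInnerIntegralGL <- function(a1, b1, a2, b2, relationship) {
  probs <- c(0, 1e-12, 1e-8, 1e-5, 0.01, 0.1, 0.5, 0.9, 0.99,
             1 - 1e-5, 1 - 1e-8, 1 - 1e-12, 1)
  brk <- unique(pmin(pmax(stats::qbeta(probs, a1, b1), 0), 1))
  brk <- sort(unique(c(0, brk, 1)))
  gl <- .gaussLegendre(64L)
  logs <- numeric(0)
  for (p in seq_len(length(brk) - 1L)) {
    lo <- brk[p]; hi <- brk[p + 1L]
    if (hi - lo <= 0) next
    x <- (hi - lo) / 2 * gl$nodes + (hi + lo) / 2
    wts <- (hi - lo) / 2 * gl$weights
    u <- if (relationship == "ancestor") x else 1 - x
    lg <- stats::dbeta(x, a1, b1, log = TRUE) +
      stats::pbeta(u, a2, b2, log.p = TRUE)
    keep <- is.finite(lg)
    if (any(keep)) logs <- c(logs, lg[keep] + log(wts[keep]))
  }
  if (!length(logs)) return(-745)  # below double underflow; effectively zero
  m <- max(logs)
  m + log(sum(exp(logs - m)))
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch (symmetric
# tridiagonal eigendecomposition); cached per order
.glCache <- new.env(parent = emptyenv())
.gaussLegendre <- function(k) {
  key <- as.character(k)
  if (!is.null(.glCache[[key]])) return(.glCache[[key]])
  i <- seq_len(k - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = rev(e$values), weights = rev(2 * e$vectors[1L, ]^2))
  .glCache[[key]] <- res
  res
}

#' Pair markers for sequential density updates
#'
#' The Bayesian update acts on marker pairs; for panels larger than two this
#' forms disjoint pairs (a matching; one marker is left unpaired for odd
#' panels). The default greedy strategy repeatedly takes the unused pair whose
#' lineage relationship is most heterogeneous across the density (weighted
#' Gini impurity of the relationship distribution), so each pair carries
#' maximal topology information; \code{"consecutive"} pairs markers in panel
#' order.
#'
#' @param panel a [MarkerPanel-class] (n >= 2 for a non-empty pairing).
#' @param density a [TreeDensity-class].
#' @param strategy \code{"greedy"} (default) or \code{"consecutive"}.
#' @return list of integer pairs (indices into the panel); unpaired marker
#'   reported via attribute \code{"unpaired"}.
#' @export
choosePairs <- function(panel, density, strategy = c("greedy", "consecutive")) {
  strategy <- match.arg(strategy)
  n <- length(panel)
  if (n < 2L) {
    warning("fewer than two markers: no pairs to update with")
    return(structure(list(), unpaired = seq_len(n)))
  }
  if (strategy == "consecutive") {
    pairs <- lapply(seq_len(n %/% 2L), function(i) c(2L * i - 1L, 2L * i))
    unpaired <- if (n %% 2L) n else integer(0)
    return(structure(pairs, unpaired = unpaired))
  }
  trs <- trees(density)
  w <- treeWeights(density)
  ids <- markerIds(panel)
  score <- matrix(-Inf, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rels <- vapply(trs, pairRelationship, character(1), ids[i], ids[j])
      p <- tapply(w, rels, sum)
      score[i, j] <- 1 - sum((p / sum(p))^2)
    }
  }
  used <- logical(n)
  pairs <- list()
  repeat {
    free <- which(!used)
    if (length(free) < 2L) break
    sub <- score[free, free, drop = FALSE]
    bst <- which(sub == max(sub), arr.ind = TRUE)
    bst <- bst[order(bst[, 1L], bst[, 2L]), , drop = FALSE][1L, ]
    pr <- c(free[bst[1L]], free[bst[2L]])
    pairs[[length(pairs) + 1L]] <- pr
    used[pr] <- TRUE
  }
  structure(pairs, unpaired = which(!used))
}

#' Bayesian update of tree-density weights from marker read counts
#'
#' Multiplies each tree's weight by the marginal likelihood of the observed
#' high-precision read counts for each marker pair under that tree's
#' relationship for the pair ([pairIntegralLog()]), then renormalizes. Pairs
#' are applied sequentially; since the per-pair multipliers commute, the order
#' of disjoint pairs does not affect the posterior.
#'
#' @param density a normalized [TreeDensity-class].
#' @param panel a [MarkerPanel-class].
#' @param counts a data.frame with columns \code{marker_id},
#'   \code{variant_reads}, \code{depth} (one row per panel marker; rows for a
#'   single time point).
#' @param pairing list of panel-index pairs, e.g. from [choosePairs()];
#'   default greedy pairing. An empty pairing returns the density unchanged.
#' @return the updated, renormalized [TreeDensity-class].
#' @export
updateWeights <- function(density, panel, counts, pairing = NULL) {
  density <- normalizeDensity(density)
  if (is.null(pairing)) pairing <- choosePairs(panel, density)
  if (!length(pairing)) return(density)
  ids <- markerIds(panel)
  row <- match(ids, counts$marker_id)
  if (anyNA(row)) {
    stop("counts missing for marker(s): ", paste(ids[is.na(row)], collapse = ", "))
  }
  r <- counts$variant_reads[row]
  d <- counts$depth[row]
  trs <- trees(density)
  logw <- log(treeWeights(density))
  for (pr in pairing) {
    i <- pr[1L]; j <- pr[2L]
    rels <- vapply(trs, pairRelationship, character(1), ids[i], ids[j])
    # one integral per distinct relationship, shared across trees
    ll <- vapply(unique(rels), pairIntegralLog, numeric(1),
                 r1 = r[i], d1 = d[i], r2 = r[j], d2 = d[j])
    logw <- logw + unname(ll[rels])
  }
  if (all(!is.finite(logw))) {
    stop("degenerate posterior: all tree weights underflowed; counts r=(",
         paste(r, collapse = ","), "), d=(", paste(d, collapse = ","), ")")
  }
  m <- max(logw[is.finite(logw)])
  w <- exp(logw - m)
  w[!is.finite(w)] <- 0
  density@weights <- w / sum(w)
  density
}
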