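# Exact cardinality-constrained subset optimization.
#
# Both marker-selection problems reduce to choosing exactly n of N items to
# maximize either (i) a linear + nonnegative-pairwise objective
# sum(c[z]) + sum(Q[z, z]) or (ii) an arbitrary monotone set function.
# Solved exactly by depth-first branch-and-bound with admissible upper bounds;
# exhaustive enumeration is available for small instances and serves as an
# independent oracle in the test suite.

.BB_TOL <- 1e-9
.BB_INIT_SLACK <- 1e-7

# enumerate all C(N, n) subsets; returns list(best = indices, value = score)
.exhaustiveMax <- function(scoreFun, N, n, limit = 2e5) {
  if (choose(N, n) > limit) {
    stop(sprintf("exhaustive search over C(%d, %d) subsets exceeds limit", N, n))
  }
  best <- NULL
  bestVal <- -Inf
  sets <- utils::combn(N, n)
  for (j in seq_len(ncol(sets))) {
    v <- scoreFun(sets[, j])
    if (v > bestVal + .BB_TOL) {
      bestVal <- v
      best <- sets[, j]
    }
  }
  list(best = best, value = bestVal)
}

# greedy forward selection (incumbent for branch-and-bound); lowest-index
# tie-break so a flat objective yields the lexicographically smallest panel
.greedySelect <- function(scoreFun, N, n) {
  chosen <- integer(0)
  for (step in seq_len(n)) {
    cand <- setdiff(seq_len(N), chosen)
    vals <- vapply(cand, function(i) scoreFun(c(chosen, i)), numeric(1))
    chosen <- c(chosen, cand[which.max(vals)])  # first = lowest-index maximizer
  }
  sort(chosen)
}

# Maximize sum(c[S]) + sum(Q[S, S]) over |S| = n, Q nonnegative off-diagonal.
# Bound at a node (chosen S, remaining suffix R, t more to pick):
#   f(S u T) <= f(S) + sum over i in T of [c_i + link_i(S) + P_i/2]
# with link_i(S) the pairwise mass between i and S, and P_i the sum of the
# t-1 largest symmetric pair terms between i and R \ {i}; maximizing the
# bound picks the t largest such scores. Admissible because Q >= 0.
.solvePairwiseMax <- function(cvec, Q, n) {
  N <- length(cvec)
  stopifnot(n >= 1L, n <= N)
  Qs <- Q + t(Q)
  diag(Qs) <- 0
  if (any(Qs < -1e-12)) stop("pairwise terms must be nonnegative")
  Qs[Qs < 0] <- 0
  score <- function(S) sum(cvec[S]) + sum(Qs[S, S, drop = FALSE]) / 2
  greedy <- .greedySelect(score, N, n)
  inc <- score(greedy) - .BB_INIT_SLACK
  best <- greedy

  recurse <- function(S, nextIdx, fS, linkS) {
    t <- n - length(S)
    if (t == 0L) {
      if (fS > inc + .BB_TOL) {
        inc <<- fS
        best <<- S
      }
      return(invisible(NULL))
    }
    R <- nextIdx:N
    if (length(R) < t) return(invisible(NULL))
    g <- cvec[R] + linkS[R]
    if (t > 1L) {
      for (ii in seq_along(R)) {
        qr <- Qs[R[ii], R[-ii]]
        P <- if (length(qr) >= t - 1L) {
          sum(sort(qr, decreasing = TRUE)[seq_len(t - 1L)])
        } else sum(qr)
        g[ii] <- g[ii] + P / 2
      }
    }
    ub <- fS + sum(sort(g, decreasing = TRUE)[seq_len(t)])
    if (ub <= inc + .BB_TOL) return(invisible(NULL))
    i <- nextIdx
    # include i
    recurse(c(S, i), i + 1L, fS + cvec[i] + linkS[i], linkS + Qs[, i])
    # exclude i
    if (N - i >= t) recurse(S, i + 1L, fS, linkS)
    invisible(NULL)
  }
  recurse(integer(0), 1L, 0, numeric(N))
  list(best = sort(best), value = score(sort(best)))
}

# Maximize a monotone nondecreasing set function over |S| = n. Bound:
# f(S u R) for the whole remaining suffix R (valid by monotonicity).
.solveMonotoneMax <- function(scoreFun, N, n) {
  stopifnot(n >= 1L, n <= N)
  greedy <- .greedySelect(scoreFun, N, n)
  inc <- scoreFun(greedy) - .BB_INIT_SLACK
  best <- greedy

  recurse <- function(S, nextIdx) {
    t <- n - length(S)
    if (t == 0L) {
      v <- scoreFun(S)
      if (v > inc + .BB_TOL) {
        inc <<- v
        best <<- S
      }
      return(invisible(NULL))
    }
    if (N - nextIdx + 1L < t) return(invisible(NULL))
    ub <- scoreFun(c(S, nextIdx:N))
    if (ub <= inc + .BB_TOL) return(invisible(NULL))
    recurse(c(S, nextIdx), nextIdx + 1L)
    recurse(S, nextIdx + 1L)
    invisible(NULL)
  }
  recurse(integer(0), 1L)
  list(best = sort(best), value = scoreFun(sort(best)))
}

# Group mutations by their per-tree clone profile: two mutations assigned to
# the same clone in every tree of the density are exchangeable in both
# selection objectives, so optimization can run over profile groups. Groups
# are ordered by their smallest mutation index.
.mutationProfiles <- function(density) {
  trs <- trees(density)
  ids <- mutationIds(trs[[1L]])
  prof <- vapply(trs, function(t) t@mutClone[match(ids, mutationIds(t))],
                 integer(length(ids)))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = length(ids))
  key <- apply(prof, 1L, paste, collapse = ".")
  gid <- match(key, unique(key))  # unique() keeps first-occurrence order,
                                  # so groups are sorted by smallest member
  members <- split(seq_along(ids), gid)
  list(gid = gid, members = lapply(members, sort))
}

.lexLess <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

# smallest member indices realizing a per-group count vector
.realizeCounts <- function(members, nvec) {
  sort(unlist(Map(function(m, k) m[seq_len(k)], members, nvec),
              use.names = FALSE))
}

# Exact maximization of sum(cg * nv) + nv' Qg nv over integer count vectors
# nv with sum(nv) = n and nv <= group sizes, by capped enumeration. Returns
# NULL when the enumeration would be too large (caller falls back to the
# ungrouped branch-and-bound). Among near-ties (within .BB_TOL) the
# lexicographically smallest realized panel wins.
.solveGroupedPairwise <- function(cg, Qg, members, n, limit = 2e5) {
  G <- length(cg)
  sizes <- vapply(members, length, integer(1))
  if (choose(n + G - 1, n) > limit) return(NULL)
  bestVal <- -Inf
  bestPanel <- NULL
  nv <- integer(G)
  recurse <- function(g, left) {
    if (g > G) {
      if (left > 0L) return(invisible(NULL))
      v <- sum(cg * nv) + drop(nv %*% Qg %*% nv)
      if (v > bestVal + .BB_TOL) {
        bestVal <<- v
        bestPanel <<- .realizeCounts(members, nv)
      } else if (v > bestVal - .BB_TOL) {
        cand <- .realizeCounts(members, nv)
        if (.lexLess(cand, bestPanel)) bestPanel <<- cand
      }
      return(invisible(NULL))
    }
    if (sum(sizes[g:G]) < left) return(invisible(NULL))
    for (k in min(left, sizes[g]):0L) {
      nv[g] <<- k
      recurse(g + 1L, left - k)
    }
    nv[g] <<- 0L
    invisible(NULL)
  }
  recurse(1L, n)
  list(best = bestPanel, value = bestVal)
}

# Exact selection of m = min(n, G) profile groups maximizing the tracked
# clonal mass (duplicate markers within a group add nothing and more groups
# never hurt, so some optimum uses exactly m distinct groups).
#
# profMat[k, g]: clone of tree k hit by group g; wtsList[[k]]: tree-weighted
# clone masses; childrenList[[k]]: children per clone. Small instances are
# enumerated with vectorized per-clone coverage tests; larger partial-mode
# instances use branch-and-bound with the submodular top-gains bound (the
# partial objective is weighted coverage, hence monotone submodular); larger
# complete-mode instances fall back to the monotone add-all-remaining bound.
.trackingGroupSolver <- function(profMat, wtsList, childrenList, n, mode,
                                 limit = 1e5) {
  K <- nrow(profMat)
  G <- ncol(profMat)
  m <- min(n, G)
  scoreGroups <- function(Sg) {
    tot <- 0
    for (k in seq_len(K)) {
      hit <- unique(profMat[k, Sg])
      if (mode == "complete") {
        hit <- hit[vapply(hit, function(c0) {
          all(childrenList[[k]][[c0]] %in% profMat[k, Sg])
        }, logical(1))]
      }
      tot <- tot + sum(wtsList[[k]][hit])
    }
    tot
  }
  if (choose(G, m) <= limit) {
    combs <- utils::combn(G, m)
    M <- ncol(combs)
    val <- numeric(M)
    for (k in seq_len(K)) {
      cl <- matrix(profMat[k, combs], nrow = m)
      wts <- wtsList[[k]]
      covered <- lapply(seq_along(wts), function(c0) {
        colSums(cl == c0) > 0L
      })
      for (c0 in seq_along(wts)) {
        if (wts[c0] == 0) next
        ok <- covered[[c0]]
        if (mode == "complete") {
          for (ch in childrenList[[k]][[c0]]) ok <- ok & covered[[ch]]
        }
        val <- val + wts[c0] * ok
      }
    }
    j <- which.max(val)  # first maximum: lexicographically smallest subset
    return(list(groups = combs[, j], value = val[j]))
  }
  if (mode == "partial") {
    sol <- .solveSubmodularCoverMax(profMat, wtsList, m)
  } else {
    sol <- .solveMonotoneMax(scoreGroups, G, m)
  }
  list(groups = sol$best, value = sol$value)
}

# Exact branch-and-bound for the partial-information (weighted-coverage)
# objective over profile groups: monotone submodular, so
# f(S u T) <= f(S) + sum of the |T| largest marginal gains at S — an
# admissible bound. Items are branched best-gain-first.
.solveSubmodularCoverMax <- function(profMat, wtsList, m) {
  K <- nrow(profMat)
  G <- ncol(profMat)
  gainTab <- function(coveredList, R) {
    g <- numeric(length(R))
    for (k in seq_len(K)) {
      w <- wtsList[[k]][profMat[k, R]]
      w[coveredList[[k]][profMat[k, R]]] <- 0
      g <- g + w
    }
    g
  }
  newCover <- function(coveredList, item) {
    for (k in seq_len(K)) coveredList[[k]][profMat[k, item]] <- TRUE
    coveredList
  }
  empty <- lapply(seq_len(K), function(k) {
    rep(FALSE, length(wtsList[[k]]))
  })
  # greedy incumbent
  cov <- empty
  S <- integer(0)
  fS <- 0
  for (step in seq_len(m)) {
    R <- setdiff(seq_len(G), S)
    g <- gainTab(cov, R)
    j <- R[which.max(g)]
    fS <- fS + max(g)
    S <- c(S, j)
    cov <- newCover(cov, j)
  }
  inc <- fS - .BB_INIT_SLACK
  best <- sort(S)
  bestVal <- fS

  recurse <- function(S, cov, fS, R) {
    t <- m - length(S)
    if (t == 0L) {
      if (fS > inc + .BB_TOL) {
        inc <<- fS
        bestVal <<- fS
        best <<- sort(S)
      }
      return(invisible(NULL))
    }
    if (length(R) < t) return(invisible(NULL))
    g <- gainTab(cov, R)
    ub <- fS + sum(sort(g, decreasing = TRUE)[seq_len(t)])
    if (ub <= inc + .BB_TOL) return(invisible(NULL))
    i <- which.max(g)
    item <- R[i]
    recurse(c(S, item), newCover(cov, item), fS + g[i], R[-i])
    recurse(S, cov, fS, R[-i])
    invisible(NULL)
  }
  recurse(integer(0), empty, 0, seq_len(G))
  list(best = best, value = bestVal)
}

.resolveSolverMode <- function(solverMode, N, n) {
  solverMode <- match.arg(solverMode, c("auto", "exact", "exhaustive"))
  if (solverMode == "auto") {
    if (choose(N, n) <= 5e3) "exhaustive" else "exact"
  } else solverMode
}
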