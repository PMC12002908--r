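# Fixture builders used across the suite. All fixtures are constructed in
# code; random instances always take an explicit seed.

# linear chain c1 -> c2 -> ... with one mutation per clone and given
# subtree-sum frequencies (single sample named "blood")
chainTree <- function(fvals, mutPerClone = 1L) {
  n <- length(fvals)
  parent <- c(NA_integer_, seq_len(n - 1L))
  mutClone <- rep(seq_len(n), each = mutPerClone)
  ClonalTree(parent, mutClone,
             matrix(fvals, 1, n, dimnames = list("blood", NULL)))
}

# random valid clonal tree over a fixed mutation universe; frequencies are
# built from Dirichlet exclusive fractions so the sum rule holds exactly
randomTree <- function(seed, nClones = 5L, nMut = 8L, nSamples = 1L,
                       mutIds = paste0("m", seq_len(nMut))) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(seq_len(nClones - 1L) + 1L,
                                  function(i) sample.int(i - 1L, 1L),
                                  integer(1)))
  stopifnot(nMut >= nClones)
  mutClone <- c(sample.int(nClones),  # one mutation per clone first
                sample.int(nClones, nMut - nClones, replace = TRUE))
  Fm <- matrix(0, nSamples, nClones,
               dimnames = list(paste0("s", seq_len(nSamples)), NULL))
  for (s in seq_len(nSamples)) {
    g <- stats::rgamma(nClones, 1)
    phi <- g / sum(g)
    # subtree sums bottom-up
    depth <- integer(nClones)
    for (i in seq_len(nClones)) {
      v <- i
      while (!is.na(parent[v])) { depth[i] <- depth[i] + 1L; v <- parent[v] }
    }
    f <- phi
    for (i in order(depth, decreasing = TRUE)) {
      if (!is.na(parent[i])) f[parent[i]] <- f[parent[i]] + f[i]
    }
    Fm[s, ] <- f
  }
  rownames(Fm)[1] <- "blood"
  ClonalTree(parent, mutClone, Fm, mutIds = mutIds)
}

# density of K random trees over one shared mutation universe
randomDensity <- function(seed, K = 3L, nClones = 5L, nMut = 8L,
                          counts = NULL) {
  trs <- lapply(seq_len(K), function(k) {
    randomTree(seed + 97L * k, nClones = nClones, nMut = nMut)
  })
  TreeDensity(trs, counts = counts, deduplicate = FALSE)
}

# independent reachability oracle: transitive closure of the parent matrix by
# boolean matrix powers, lifted to mutations with the same-clone convention
bruteForceAncestorMatrix <- function(tree) {
  E <- parentMatrix(tree)
  n <- nrow(E)
  reach <- matrix(FALSE, n, n)
  P <- diag(n)
  for (step in seq_len(n)) {
    P <- (P %*% E) > 0
    reach <- reach | P
  }
  cl <- cloneOf(tree, seq_len(nMutations(tree)))
  A <- matrix(0L, nMutations(tree), nMutations(tree))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (i == j) next
      if (cl[i] == cl[j] || reach[cl[i], cl[j]]) A[i, j] <- 1L
    }
  }
  dimnames(A) <- list(mutationIds(tree), mutationIds(tree))
  A
}

# test-side quadrature oracle for the pairwise marginal likelihood:
# nested numerical integration of beta-density-rescaled integrands (the
# rescaling avoids underflow; both integrals are still evaluated numerically,
# independently of the package's incomplete-beta path)
oraclePairIntegral <- function(relationship, r1, d1, r2, d2) {
  logbin <- lchoose(d1, r1) + lchoose(d2, r2)
  if (relationship == "same_clone") {
    a <- r1 + r2 + 1; b <- d1 + d2 - r1 - r2 + 1
    val <- stats::integrate(function(f) stats::dbeta(f, a, b), 0, 1,
                            rel.tol = 1e-10)$value
    return(exp(logbin + lbeta(a, b)) * val)
  }
  if (relationship == "descendant") {
    return(oraclePairIntegral("ancestor", r2, d2, r1, d1))
  }
  a1 <- r1 + 1; b1 <- d1 - r1 + 1
  a2 <- r2 + 1; b2 <- d2 - r2 + 1
  outer2 <- function(f1) {
    vapply(f1, function(x) {
      hi <- if (relationship == "ancestor") x else 1 - x
      if (hi <= 0) return(0)
      stats::integrate(function(f2) stats::dbeta(f2, a2, b2), 0, hi,
                       rel.tol = 1e-10)$value
    }, numeric(1))
  }
  val <- stats::integrate(function(f1) {
    stats::dbeta(f1, a1, b1) * outer2(f1)
  }, 0, 1, rel.tol = 1e-9)$value
  exp(logbin + lbeta(a1, b1) + lbeta(a2, b2)) * val
}
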