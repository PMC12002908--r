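test_that("ancestor matrix encodes the four pairwise relationships", {
  # chain: m1 in root, m2 in child
  tr <- chainTree(c(0.8, 0.3))
  A <- ancestorMatrix(tr)
  expect_equal(A["m1", "m2"], 1L)
  expect_equal(A["m2", "m1"], 0L)

  # two mutations in one clone are mutual ancestors, diagonal stays zero
  tr2 <- ClonalTree(NA_integer_, c(1L, 1L), matrix(1, 1, 1))
  A2 <- ancestorMatrix(tr2)
  expect_equal(A2["m1", "m2"], 1L)
  expect_equal(A2["m2", "m1"], 1L)
  expect_equal(diag(A2), c(m1 = 0L, m2 = 0L))

  # siblings on different branches share no ancestry
  tr3 <- ClonalTree(c(NA, 1L, 1L), c(1L, 2L, 3L),
                    matrix(c(0.9, 0.4, 0.3), 1, 3))
  A3 <- ancestorMatrix(tr3)
  expect_equal(A3["m2", "m3"], 0L)
  expect_equal(A3["m3", "m2"], 0L)
})

test_that("ancestor matrix equals brute-force reachability on random trees", {
  for (seed in 1:20) {
    nc <- 2L + (seed %% 7L)
    tr <- randomTree(seed, nClones = nc, nMut = nc + 4L)
    expect_identical(ancestorMatrix(tr), bruteForceAncestorMatrix(tr))
  }
})

test_that("panel projection restricts the ancestor matrix", {
  tr <- chainTree(c(0.9, 0.5, 0.2))  # m1 -> m2 -> m3
  A <- ancestorMatrix(tr)
  expect_identical(projectPanel(A, seq_len(3)), A)
  expect_identical(unname(projectPanel(A, 2L)), matrix(0L, 1, 1))
  expect_identical(unname(projectPanel(A, c(1L, 3L))),
                   matrix(c(0L, 0L, 1L, 0L), 2, 2))
  expect_error(projectPanel(A, 9L), "out of range")
})

test_that("clone fractions subtract children and conserve total mass", {
  expect_equal(unname(cloneFractions(chainTree(c(0.8, 0.3)), "blood")),
               c(0.5, 0.3))
  expect_equal(unname(cloneFractions(chainTree(1.0))), 1.0)
  tr <- ClonalTree(c(NA, 1L, 1L), c(1L, 2L, 3L),
                   matrix(c(0.9, 0.4, 0.3), 1, 3))
  expect_equal(unname(cloneFractions(tr))[1], 0.2)

  # conservation: exclusive fractions sum to the root's subtree frequency
  for (seed in 1:10) {
    tr <- randomTree(seed, nClones = 6L, nMut = 6L)
    fb <- cloneFractions(tr, "blood")
    expect_equal(sum(fb), cloneFrequencies(tr)["blood", rootClone(tr)])
  }
})

test_that("sum-rule violations beyond tolerance are rejected", {
  expect_error(
    ClonalTree(c(NA, 1L), c(1L, 2L), matrix(c(0.3, 0.8), 1, 2)),
    "sum rule")
  # within tolerance: clipped, not an error
  tr <- ClonalTree(c(NA, 1L), c(1L, 2L),
                   matrix(c(0.3, 0.3 + 1e-9), 1, 2))
  expect_true(all(cloneFractions(tr) >= 0))
})

test_that("malformed tree structures are rejected", {
  good <- matrix(c(0.9, 0.4), 1, 2)
  expect_error(ClonalTree(c(2L, 1L), c(1L, 2L), good), "root")
  expect_error(ClonalTree(c(NA, NA), c(1L, 2L), good), "root")
  expect_error(ClonalTree(c(NA, 5L), c(1L, 2L), good))
  expect_error(ClonalTree(c(NA, 1L), c(1L, 3L), good), "nonexistent")
  expect_error(ClonalTree(c(NA, 1L), c(1L, 2L),
                          matrix(c(1.4, 0.4), 1, 2)), "\\[0, 1\\]")
})

test_that("pair relationship matches the ancestor-matrix convention", {
  tr <- chainTree(c(0.8, 0.3))
  expect_equal(pairRelationship(tr, "m1", "m2"), "ancestor")
  expect_equal(pairRelationship(tr, "m2", "m1"), "descendant")
  sib <- ClonalTree(c(NA, 1L, 1L), c(1L, 2L, 3L),
                    matrix(c(0.9, 0.4, 0.3), 1, 3))
  expect_equal(pairRelationship(sib, 2L, 3L), "branched")
  same <- ClonalTree(NA_integer_, c(1L, 1L), matrix(1, 1, 1))
  expect_equal(pairRelationship(same, 1L, 2L), "same_clone")
  expect_error(pairRelationship(tr, 1L, 1L), "itself")

  # swap antisymmetry / symmetry on random trees
  for (seed in 1:8) {
    tr <- randomTree(seed + 40L, nClones = 5L, nMut = 7L)
    for (i in 1:6) {
      r12 <- pairRelationship(tr, i, i + 1L)
      r21 <- pairRelationship(tr, i + 1L, i)
      if (r12 %in% c("same_clone", "branched")) {
        expect_equal(r21, r12)
      } else {
        expect_equal(sort(c(r12, r21)), c("ancestor", "descendant"))
      }
    }
  }
})

test_that("density weights normalize from counts and are idempotent", {
  d <- randomDensity(1, K = 2L)
  d@counts <- c(60, 40)
  d@weights <- c(60, 40)
  d <- normalizeDensity(d)
  expect_equal(treeWeights(d), c(0.6, 0.4))
  expect_equal(treeWeights(normalizeDensity(d)), c(0.6, 0.4))

  d3 <- randomDensity(2, K = 3L)
  d3@weights <- c(2, 2, 4)
  expect_equal(treeWeights(normalizeDensity(d3)), c(0.25, 0.25, 0.5))

  single <- TreeDensity(list(randomTree(3)))
  expect_equal(treeWeights(single), 1.0)

  bad <- randomDensity(4, K = 2L)
  bad@weights <- c(0, 0)
  expect_error(normalizeDensity(bad), "degenerate")
})

test_that("bootstrap replicates of one topology merge with accumulated counts", {
  tr <- randomTree(11, nClones = 4L, nMut = 6L)
  # same topology, different clone ordering: permute clones 2..4
  perm <- c(1L, 4L, 2L, 3L)
  inv <- match(seq_len(4L), perm)
  tr2 <- ClonalTree(ifelse(is.na(tr@parent[perm]), NA_integer_,
                           inv[tr@parent[perm]]),
                    inv[cloneOf(tr, seq_len(6))],
                    cloneFrequencies(tr)[, perm, drop = FALSE],
                    mutIds = mutationIds(tr))
  other <- randomTree(12, nClones = 4L, nMut = 6L)
  d <- TreeDensity(list(tr, tr2, other))
  expect_equal(length(d), 2L)
  expect_equal(sort(treeCounts(d)), c(1, 2))
  expect_equal(sum(treeCounts(d)), 3)
})

test_that("marker panels reject duplicates and resolve ids", {
  expect_error(MarkerPanel(c(2L, 2L)), "duplicate")
  p <- MarkerPanel(c("m3", "m1"), universe = paste0("m", 1:5))
  expect_equal(markerIndices(p), c(3L, 1L))
  expect_equal(markerIds(p), c("m3", "m1"))
  expect_error(MarkerPanel("mX", universe = paste0("m", 1:5)), "unknown")
})
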