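test_that("gaussian read moments follow the binomial approximation", {
  tr <- chainTree(c(0.3, 0.1))
  g <- gaussianMoments(tr, 1L, structureParams(depth = 1000))
  expect_equal(g$mu, 300)
  expect_equal(g$sigma2, 210)

  tr5 <- chainTree(c(0.5, 0.1))
  g5 <- gaussianMoments(tr5, 1L, structureParams(depth = 100))
  expect_equal(g5$mu, 50)
  expect_equal(g5$sigma2, 25)

  # degenerate frequency: variance floored, never zero
  tr0 <- ClonalTree(c(NA, 1L), c(1L, 2L), matrix(c(0.5, 0), 1, 2,
                                                 dimnames = list("blood", NULL)))
  g0 <- gaussianMoments(tr0, 2L, structureParams(depth = 1000))
  expect_equal(g0$mu, 0)
  expect_equal(g0$sigma2, 1e-6 * 1000)
})

test_that("pair divergence matches a direct scalar evaluation", {
  params <- structureParams(depth = 100, lambda = 3)
  # identical trees: structure term zero, read term the panel's constant
  tr <- chainTree(c(0.8, 0.4, 0.2))
  pd <- pairDivergence(tr, tr, seq_len(3), params, components = TRUE)
  expect_equal(pd$structure, 0)
  s2 <- 100 * c(0.8, 0.4, 0.2) * c(0.2, 0.6, 0.8)
  expect_equal(pd$read, -0.5 * sum(log(4 * pi * s2)))

  # lambda = 1 silences the structure component for any tree pair
  trA <- chainTree(c(0.8, 0.4))
  trB <- ClonalTree(c(NA, 1L), c(2L, 1L), matrix(c(0.8, 0.4), 1, 2,
                                                 dimnames = list("blood", NULL)))
  p1 <- structureParams(depth = 100, lambda = 1)
  expect_equal(pairDivergence(trA, trB, 1:2, p1, components = TRUE)$structure, 0)

  # hand-set chains differing in one marker's clone, against the printed
  # formula evaluated with plain scalars
  fA <- c(0.7, 0.3); fB <- c(0.7, 0.7)   # m2 moves from child to root
  trA <- ClonalTree(c(NA, 1L), c(1L, 2L),
                    matrix(fA, 1, 2, dimnames = list("blood", NULL)))
  trB <- ClonalTree(c(NA, 1L), c(1L, 1L),
                    matrix(c(0.7, 0.2), 1, 2, dimnames = list("blood", NULL)))
  D <- 100
  muA <- D * fA; muB <- D * fB
  s2A <- D * fA * (1 - fA); s2B <- D * fB * (1 - fB)
  readExp <- -0.5 * sum(log(2 * pi * (s2A + s2B))) -
    0.5 * sum((muB - muA)^2 / (s2A + s2B))
  # ancestor matrices: A: m1->m2 chain; B: same clone (mutual)
  structExp <- log(3) * (abs(1 - 1) + abs(1 - 0))  # entries (1,2) and (2,1)
  got <- pairDivergence(trA, trB, 1:2, structureParams(depth = 100, lambda = 3))
  expect_equal(got, readExp + structExp, tolerance = 1e-12)
})

test_that("structure objective matches its ordered-pair definition", {
  params <- structureParams(depth = 200, lambda = 2)
  dens <- randomDensity(5, K = 3L, nClones = 4L, nMut = 4L)
  dens@weights <- c(0.5, 0.3, 0.2)
  # independent oracle: explicit double loop over ordered tree pairs with the
  # discriminative sign applied to the read component
  oracle <- function(panel) {
    tot <- 0
    w <- treeWeights(dens)
    for (q in 1:3) for (k in 1:3) {
      if (q == k) next
      pd <- pairDivergence(dens[[q]], dens[[k]], panel, params,
                           components = TRUE)
      tot <- tot + w[q] * w[k] * (-pd$read + pd$structure)
    }
    tot
  }
  sets <- utils::combn(4L, 2L)
  for (j in seq_len(ncol(sets))) {
    expect_equal(structureObjective(dens, sets[, j], params),
                 oracle(sets[, j]), tolerance = 1e-10)
  }
})

test_that("two identical trees contribute no structure term and lambda is log-linear", {
  tr <- randomTree(21, nClones = 4L, nMut = 5L)
  dens <- TreeDensity(list(tr, tr), deduplicate = FALSE)
  p2 <- structureParams(depth = 100, lambda = 2)
  co <- phyloMarkers:::.structureCoefficients(dens, p2)
  expect_equal(sum(co$Q), 0)

  # doubling lambda adds log(2) * sum|dA| per weighted ordered pair
  densAB <- randomDensity(31, K = 2L, nClones = 4L, nMut = 5L)
  pan <- 1:3
  s2 <- structureObjective(densAB, pan, structureParams(depth = 100, lambda = 2))
  s4 <- structureObjective(densAB, pan, structureParams(depth = 100, lambda = 4))
  dA <- sum(abs(projectPanel(ancestorMatrix(densAB[[1]]), pan) -
                projectPanel(ancestorMatrix(densAB[[2]]), pan)))
  expect_equal(s4 - s2, 2 * 0.25 * log(2) * dA, tolerance = 1e-10)
})

test_that("selection returns the lexicographically smallest optimal panel", {
  # single tree: all panels tie, smallest indices win
  dens <- TreeDensity(list(randomTree(41, nClones = 4L, nMut = 6L)))
  params <- structureParams(depth = 100, lambda = 2)
  suppressWarnings({
    p <- selectStructureMarkers(dens, 3L, params)
  })
  expect_equal(markerIndices(p), 1:3)
})

test_that("a mutation whose placement differs across trees is selected", {
  # two trees identical except mutation g3 moves clone; equal frequencies
  F1 <- matrix(c(0.9, 0.5, 0.3), 1, 3, dimnames = list("blood", NULL))
  trA <- ClonalTree(c(NA, 1L, 2L), c(1L, 2L, 3L, 1L), F1)   # m3 in clone 3
  trB <- ClonalTree(c(NA, 1L, 2L), c(1L, 2L, 2L, 1L), F1)   # m3 in clone 2
  dens <- TreeDensity(list(trA, trB), deduplicate = FALSE)
  params <- structureParams(depth = 100, lambda = 4)
  p <- selectStructureMarkers(dens, 2L, params)
  expect_true(3L %in% markerIndices(p))
})

test_that("exact solver equals the exhaustive oracle on random densities", {
  params <- structureParams(depth = 500, lambda = 3)
  for (seed in c(7, 8, 9, 10)) {
    dens <- randomDensity(seed, K = 4L, nClones = 5L, nMut = 10L)
    pEx <- selectStructureMarkers(dens, 3L, params, solverMode = "exhaustive")
    pBB <- selectStructureMarkers(dens, 3L, params, solverMode = "exact")
    expect_equal(structureObjective(dens, pBB, params),
                 structureObjective(dens, pEx, params), tolerance = 1e-8)
  }
})

test_that("objective is equivariant under mutation relabeling", {
  dens <- randomDensity(55, K = 3L, nClones = 4L, nMut = 6L)
  params <- structureParams(depth = 300, lambda = 2)
  perm <- c(4L, 6L, 1L, 3L, 2L, 5L)
  permuteTree <- function(t) {
    ClonalTree(t@parent, cloneOf(t, perm), cloneFrequencies(t),
               mutIds = paste0("m", 1:6))
  }
  densP <- TreeDensity(lapply(trees(dens), permuteTree), deduplicate = FALSE)
  for (j in 1:5) {
    set.seed(j)
    pan <- sort(sample.int(6L, 3L))
    expect_equal(structureObjective(densP, match(pan, perm), params),
                 structureObjective(dens, pan, params), tolerance = 1e-9)
  }
})

test_that("with lambda 1 and shared F and M all panels score equally", {
  tr <- randomTree(61, nClones = 4L, nMut = 6L)
  dens <- TreeDensity(list(tr, tr), deduplicate = FALSE)
  # discriminating parts only (the Gaussian normalization constant is a
  # panel-dependent offset unrelated to tree separation)
  params <- structureParams(depth = 100, lambda = 1, includeConstant = FALSE)
  sets <- utils::combn(6L, 2L)
  vals <- vapply(seq_len(ncol(sets)), function(j) {
    structureObjective(dens, sets[, j], params)
  }, numeric(1))
  expect_equal(vals, rep(0, ncol(sets)))
})
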