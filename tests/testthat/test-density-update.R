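test_that("zero-count integrals recover region areas exactly", {
  expect_equal(exp(pairIntegralLog("same_clone", 0, 0, 0, 0)), 1)
  expect_equal(exp(pairIntegralLog("ancestor", 0, 0, 0, 0)), 0.5,
               tolerance = 1e-10)
  expect_equal(exp(pairIntegralLog("descendant", 0, 0, 0, 0)), 0.5,
               tolerance = 1e-10)
  expect_equal(exp(pairIntegralLog("branched", 0, 0, 0, 0)), 0.5,
               tolerance = 1e-10)
})

test_that("same-clone integral matches the Beta closed form", {
  # worked example: r = (1, 0), d = (1, 1) gives B(2, 2) = 1/6
  expect_equal(exp(pairIntegralLog("same_clone", 1, 1, 0, 1)), 1 / 6,
               tolerance = 1e-12)
  # independent quadrature oracle over random count draws
  set.seed(42)
  for (i in 1:200) {
    d1 <- sample.int(60, 1); d2 <- sample.int(60, 1)
    r1 <- sample.int(d1 + 1L, 1) - 1L; r2 <- sample.int(d2 + 1L, 1) - 1L
    expect_equal(exp(pairIntegralLog("same_clone", r1, d1, r2, d2)),
                 oraclePairIntegral("same_clone", r1, d1, r2, d2),
                 tolerance = 1e-6)
  }
})

test_that("ordered-region integrals match quadrature and swap symmetry", {
  set.seed(7)
  for (i in 1:25) {
    d1 <- sample.int(40, 1); d2 <- sample.int(40, 1)
    r1 <- sample.int(d1 + 1L, 1) - 1L; r2 <- sample.int(d2 + 1L, 1) - 1L
    for (rel in c("ancestor", "branched")) {
      expect_equal(exp(pairIntegralLog(rel, r1, d1, r2, d2)),
                   oraclePairIntegral(rel, r1, d1, r2, d2),
                   tolerance = 1e-6)
    }
    # ancestor with swapped counts equals descendant
    expect_equal(pairIntegralLog("ancestor", r1, d1, r2, d2),
                 pairIntegralLog("descendant", r2, d2, r1, d1),
                 tolerance = 1e-10)
  }
  expect_error(pairIntegralLog("ancestor", 5, 3, 0, 1), "exceed")
})

test_that("extreme counts stay finite through the log-space fallback", {
  ll <- pairIntegralLog("ancestor", 10, 10000, 9900, 10000)
  expect_true(is.finite(ll))
  ll2 <- pairIntegralLog("branched", 9000, 10000, 8000, 10000)
  expect_true(is.finite(ll2) || ll2 < -700)
})

test_that("posterior update favors the relationship consistent with counts", {
  # tree 1 puts the markers in one clone (f1 = f2); tree 2 on branches
  t1 <- ClonalTree(NA_integer_, c(1L, 1L),
                   matrix(1, 1, 1, dimnames = list("blood", NULL)))
  t2 <- ClonalTree(c(NA, 1L, 1L), c(2L, 3L),
                   matrix(c(1, 0.6, 0.3), 1, 3,
                          dimnames = list("blood", NULL)))
  dens <- TreeDensity(list(t1, t2), deduplicate = FALSE)
  panel <- MarkerPanel(1:2, universe = c("m1", "m2"))
  counts <- data.frame(marker_id = c("m1", "m2"),
                       variant_reads = c(90, 10), depth = c(100, 100))
  post <- updateWeights(dens, panel, counts, pairing = list(c(1L, 2L)))
  expect_equal(sum(treeWeights(post)), 1)
  # exact posterior from the independent quadrature oracle
  lc <- oraclePairIntegral("same_clone", 90, 100, 10, 100)
  ld <- oraclePairIntegral("branched", 90, 100, 10, 100)
  expect_equal(treeWeights(post)[2], ld / (lc + ld), tolerance = 1e-6)
  expect_gt(treeWeights(post)[2], treeWeights(post)[1])
})

test_that("zero-information counts leave mixed densities unchanged", {
  # relationships ancestor and branched both integrate to 1/2 at zero counts
  t1 <- chainTree(c(0.8, 0.3))
  t2 <- ClonalTree(c(NA, 1L, 1L), c(2L, 3L),
                   matrix(c(1, 0.6, 0.3), 1, 3,
                          dimnames = list("blood", NULL)),
                   mutIds = c("m1", "m2"))
  dens <- TreeDensity(list(t1, t2), counts = c(3, 1), deduplicate = FALSE)
  panel <- MarkerPanel(1:2, universe = c("m1", "m2"))
  counts <- data.frame(marker_id = c("m1", "m2"),
                       variant_reads = c(0, 0), depth = c(0, 0))
  post <- updateWeights(dens, panel, counts, pairing = list(c(1L, 2L)))
  expect_equal(treeWeights(post), c(0.75, 0.25), tolerance = 1e-9)

  # single tree stays at weight one whatever the counts
  single <- TreeDensity(list(t1))
  counts2 <- data.frame(marker_id = c("m1", "m2"),
                        variant_reads = c(40, 10), depth = c(100, 100))
  expect_equal(treeWeights(updateWeights(single, panel, counts2,
                                         pairing = list(c(1L, 2L)))), 1.0)

  # empty pairing is the identity
  expect_equal(treeWeights(updateWeights(dens, panel, counts2,
                                         pairing = list())),
               c(0.75, 0.25))
})

test_that("disjoint pair updates commute", {
  dens <- randomDensity(77, K = 4L, nClones = 5L, nMut = 8L)
  panel <- MarkerPanel(c(1L, 3L, 5L, 7L), universe = paste0("m", 1:8))
  counts <- data.frame(marker_id = paste0("m", c(1, 3, 5, 7)),
                       variant_reads = c(70, 20, 45, 5),
                       depth = rep(100, 4))
  pAB <- updateWeights(dens, panel, counts,
                       pairing = list(c(1L, 2L), c(3L, 4L)))
  pBA <- updateWeights(dens, panel, counts,
                       pairing = list(c(3L, 4L), c(1L, 2L)))
  expect_equal(treeWeights(pAB), treeWeights(pBA), tolerance = 1e-12)
  expect_true(all(treeWeights(pAB) >= 0))
  expect_equal(sum(treeWeights(pAB)), 1)
})

test_that("pairing prefers relationship-heterogeneous marker pairs", {
  # markers m1, m2 disagree across trees; m1, m3 agree everywhere
  t1 <- ClonalTree(c(NA, 1L), c(1L, 2L, 1L, 2L),
                   matrix(c(0.9, 0.4), 1, 2, dimnames = list("blood", NULL)))
  t2 <- ClonalTree(c(NA, 1L), c(1L, 1L, 1L, 2L),
                   matrix(c(0.9, 0.4), 1, 2, dimnames = list("blood", NULL)))
  dens <- TreeDensity(list(t1, t2), deduplicate = FALSE)
  panel <- MarkerPanel(1:4, universe = paste0("m", 1:4))
  pairing <- choosePairs(panel, dens)
  expect_true(any(vapply(pairing, function(p) all(p == c(1L, 2L)), logical(1))))

  expect_warning(p1 <- choosePairs(MarkerPanel(1L), dens), "fewer than two")
  expect_length(p1, 0L)
  p3 <- choosePairs(MarkerPanel(1:3, universe = paste0("m", 1:4)), dens)
  expect_length(p3, 1L)
  expect_length(attr(p3, "unpaired"), 1L)
  # consecutive strategy pairs in panel order
  p4 <- choosePairs(panel, dens, strategy = "consecutive")
  expect_equal(p4[[1]], c(1L, 2L))
  expect_equal(p4[[2]], c(3L, 4L))
})

test_that("the truth gains posterior weight on simulated counts", {
  # ground-truth tree inside a 5-tree density; deep counts simulated from
  # the truth should (almost always) not decrease its weight
  wins <- 0L
  for (rep in 1:50) {
    trs <- lapply(1:5, function(k) {
      randomTree(1000 + 31L * rep + k, nClones = 4L, nMut = 6L)
    })
    dens <- TreeDensity(trs, deduplicate = FALSE)
    truth <- trs[[1L]]
    set.seed(2000 + rep)
    panel <- MarkerPanel(sort(sample.int(6L, 4L)),
                         universe = mutationIds(truth))
    f <- cloneFrequencies(truth)["blood", cloneOf(truth, markerIndices(panel))]
    counts <- data.frame(marker_id = markerIds(panel),
                         variant_reads = rbinom(4L, 10000L, f),
                         depth = rep(10000L, 4L))
    post <- updateWeights(dens, panel, counts)
    if (treeWeights(post)[1L] >= treeWeights(dens)[1L] - 1e-12) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 45L)
})
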