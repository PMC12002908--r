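#' Simulation configuration
#'
#' Defaults reproduce the synthetic study conditions: trees of 7 clones,
#' expected 50 mutations, one blood plus two tissue samples with per-clone
#' tissue dropout probability 0.5, and 100 bootstrap replicates per case.
#'
#' @param nClones clones per tree (>= 2).
#' @param mutationRate expected total mutation count (Poisson mean; at least
#'   one mutation per clone is enforced).
#' @param nTissue,nBlood numbers of tissue and blood samples.
#' @param maskProportion per-clone dropout probability in each tissue sample,
#'   in [0, 1).
#' @param seqDepth bulk sequencing depth per mutation.
#' @param ddpcrDepth high-precision assay depth per marker.
#' @param nBootstrap bootstrap replicates for density estimation.
#' @param attachTol slack allowed when attaching clusters under the sum rule
#'   in the bootstrap tree builder (absorbs binomial noise).
#' @param seed master seed; every stage derives its own named stream from it.
#' @return list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nClones = 7, mutationRate = 50, nTissue = 2, nBlood = 1,
                      maskProportion = 0.5, seqDepth = 1000,
                      ddpcrDepth = 10000, nBootstrap = 100,
                      attachTol = 0.05, seed = 1L) {
  stopifnot(nClones >= 2, mutationRate >= 1, nTissue >= 0, nBlood >= 0,
            maskProportion >= 0, maskProportion < 1,
            seqDepth >= 1, ddpcrDepth >= 1, nBootstrap >= 1)
  structure(list(nClones = as.integer(nClones), mutationRate = mutationRate,
                 nTissue = as.integer(nTissue), nBlood = as.integer(nBlood),
                 maskProportion = maskProportion, seqDepth = seqDepth,
                 ddpcrDepth = ddpcrDepth, nBootstrap = as.integer(nBootstrap),
                 attachTol = attachTol, seed = as.integer(seed)),
            class = "SimConfig")
}

# independent named child streams from one master seed (kept below 2^31)
.childSeed <- function(seed, stream) {
  offset <- c(tree = 11L, reads = 23L, bootstrap = 37L, ddpcr = 53L,
              drift = 71L)[[stream]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

.rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

# subtree-sum frequencies from exclusive clone fractions
.subtreeSums <- function(parent, phi) {
  n <- length(parent)
  Fm <- phi
  # accumulate children into parents; process nodes deepest-first
  depth <- integer(n)
  for (i in seq_len(n)) {
    v <- i
    while (!is.na(parent[v])) {
      depth[i] <- depth[i] + 1L
      v <- parent[v]
    }
  }
  for (i in order(depth, decreasing = TRUE)) {
    if (!is.na(parent[i])) Fm[parent[i]] <- Fm[parent[i]] + Fm[i]
  }
  Fm
}

#' Simulate a ground-truth clonal tree
#'
#' Draws a uniformly random rooted tree by sequential random-parent
#' attachment, assigns a Poisson number of mutations uniformly over clones
#' (each clone guaranteed at least one), draws exclusive clone fractions per
#' sample from a flat Dirichlet, applies per-clone dropout to tissue samples
#' (with renormalization), and computes subtree-sum frequencies.
#'
#' @param config a [simConfig()] list.
#' @return a [ClonalTree-class] with samples \code{blood}, \code{blood2}, ...,
#'   \code{tissue1}, \code{tissue2}, ...
#' @export
simulateTree <- function(config) {
  set.seed(.childSeed(config$seed, "tree"))
  n <- config$nClones
  parent <- c(NA_integer_,
              vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  N <- max(n, stats::rpois(1, config$mutationRate))
  assign <- sample.int(n, N, replace = TRUE)
  missing <- setdiff(seq_len(n), unique(assign))
  for (cl in missing) {
    rich <- which(tabulate(assign, n)[assign] > 1L)
    assign[rich[sample.int(length(rich), 1L)]] <- cl
  }
  sampleNames <- c(
    if (config$nBlood > 0) paste0("blood", c("", seq_len(config$nBlood))[
      seq_len(config$nBlood)]),
    if (config$nTissue > 0) paste0("tissue", seq_len(config$nTissue))
  )
  S <- length(sampleNames)
  Fm <- matrix(0, S, n, dimnames = list(sampleNames, NULL))
  isTissue <- grepl("^tissue", sampleNames)
  root <- 1L
  for (s in seq_len(S)) {
    phi <- .rdirichlet1(n)
    if (isTissue[s]) {
      drop <- stats::runif(n) < config$maskProportion
      drop[root] <- FALSE
      phi[drop] <- 0
      phi <- phi / sum(phi)
    }
    Fm[s, ] <- .subtreeSums(parent, phi)
  }
  ClonalTree(parent, assign, Fm)
}

#' Simulate bulk sequencing read counts
#'
#' Each mutation's variant read count is binomial at the given depth with
#' success probability equal to the mutation's subtree-sum frequency in the
#' chosen sample, independently across mutations.
#'
#' @param tree a [ClonalTree-class].
#' @param sample sample name or index.
#' @param depth sequencing depth (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns \code{mutation_id}, \code{variant_reads},
#'   \code{depth}, \code{sample}.
#' @export
simulateReads <- function(tree, sample, depth, seed) {
  set.seed(.childSeed(seed, "reads") + if (is.character(sample)) {
    match(sample, rownames(tree@F))
  } else as.integer(sample))
  Fm <- cloneFrequencies(tree)
  s <- if (is.character(sample)) match(sample, rownames(Fm)) else sample
  f <- Fm[s, tree@mutClone]
  N <- nMutations(tree)
  data.frame(mutation_id = mutationIds(tree),
             variant_reads = stats::rbinom(N, depth, f),
             depth = rep(depth, N),
             sample = rownames(Fm)[s],
             stringsAsFactors = FALSE)
}

# greedy tree construction from cluster mean VAF profiles: clusters ordered by
# overall mean VAF descending; each is attached to the compatible placed node
# (sum-rule slack in every sample, within attachTol) with the lowest mean VAF,
# i.e. the most specific placement; with no compatible node, to the node with
# the least violation. Parents are then raised to restore the sum rule exactly.
.buildTreeFromClusters <- function(centers, members, mutIds, attachTol) {
  k <- nrow(centers)
  ord <- order(rowMeans(centers), decreasing = TRUE)
  parent <- rep(NA_integer_, k)
  placed <- ord[1L]
  for (c0 in ord[-1L]) {
    slack <- vapply(placed, function(p) {
      kids <- which(!is.na(parent) & parent == p)
      min(centers[p, ] - colSums(centers[kids, , drop = FALSE]) - centers[c0, ])
    }, numeric(1))
    ok <- slack >= -attachTol
    parent[c0] <- if (any(ok)) {
      cand <- placed[ok]
      cand[which.min(rowMeans(centers)[cand])]
    } else {
      placed[which.max(slack)]
    }
    placed <- c(placed, c0)
  }
  # repair: cap at [0, 1], then walk top-down rescaling each node's children
  # so their sum never exceeds the parent - enforces the sum rule exactly
  # while keeping frequencies in range
  Fm <- t(centers)  # samples x clones
  Fm[Fm > 1] <- 1
  Fm[Fm < 0] <- 0
  depth <- integer(k)
  for (i in seq_len(k)) {
    v <- i
    while (!is.na(parent[v])) {
      depth[i] <- depth[i] + 1L
      v <- parent[v]
    }
  }
  for (p in order(depth)) {
    kids <- which(!is.na(parent) & parent == p)
    if (!length(kids)) next
    for (s in seq_len(nrow(Fm))) {
      cs <- sum(Fm[s, kids])
      if (cs > Fm[s, p] && cs > 0) {
        Fm[s, kids] <- Fm[s, kids] * (Fm[s, p] / cs)
      }
    }
  }
  ClonalTree(parent, members, Fm, mutIds = mutIds)
}

#' Estimate an empirical tree density by bootstrapping reads
#'
#' For each replicate, every mutation's reads are resampled binomially at the
#' original depth around the observed VAF; mutations are clustered by their
#' resampled multi-sample VAF profiles (k-means, k chosen by mean silhouette
#' width); clusters are assembled into a tree by the greedy sum-rule heuristic
#' and topology counts accumulate into a [TreeDensity-class]. This built-in
#' builder is a deliberately lightweight stand-in for full tumor-phylogeny
#' engines; externally inferred per-replicate trees (e.g. a PhyloWGS-style
#' summary via [readPhyloWGS()]) can be supplied instead through
#' \code{replicateTrees}.
#'
#' @param readsBySample list of data.frames as from [simulateReads()] (one
#'   per sample; same mutation order), or NULL when \code{replicateTrees} is
#'   given.
#' @param config a [simConfig()] list (uses \code{nBootstrap},
#'   \code{attachTol}, \code{seed}).
#' @param kRange candidate cluster numbers for the silhouette search.
#' @param replicateTrees optional list of [ClonalTree-class] objects, one per
#'   replicate, bypassing the built-in builder.
#' @return a [TreeDensity-class] with counts summing to the number of
#'   replicates.
#' @export
bootstrapDensity <- function(readsBySample, config, kRange = NULL,
                             replicateTrees = NULL) {
  if (!is.null(replicateTrees)) {
    return(TreeDensity(replicateTrees))
  }
  stopifnot(length(readsBySample) >= 1L)
  set.seed(.childSeed(config$seed, "bootstrap"))
  vafObs <- vapply(readsBySample,
                   function(df) df$variant_reads / pmax(df$depth, 1),
                   numeric(nrow(readsBySample[[1L]])))
  depths <- vapply(readsBySample, function(df) as.numeric(df$depth),
                   numeric(nrow(readsBySample[[1L]])))
  if (all(vafObs == 0)) stop("degenerate input: all-zero read counts")
  mutIds <- readsBySample[[1L]]$mutation_id
  N <- length(mutIds)
  if (is.null(kRange)) kRange <- 2:min(10L, N - 1L)
  treesOut <- vector("list", config$nBootstrap)
  for (b in seq_len(config$nBootstrap)) {
    v <- matrix(stats::rbinom(length(vafObs), as.vector(depths),
                              as.vector(vafObs)) / as.vector(depths),
                nrow = N)
    rownames(v) <- mutIds
    colnames(v) <- names(readsBySample)
    km <- .clusterVafProfiles(v, kRange)
    treesOut[[b]] <- .buildTreeFromClusters(km$centers, km$cluster, mutIds,
                                            config$attachTol)
  }
  TreeDensity(treesOut)
}

# k-means over VAF profiles with silhouette-selected k
.clusterVafProfiles <- function(v, kRange) {
  best <- NULL
  bestSil <- -Inf
  dmat <- stats::dist(v)
  for (k in kRange) {
    if (k >= nrow(v)) next
    km <- tryCatch(stats::kmeans(v, centers = k, nstart = 3L, iter.max = 30L),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2L) next
    sil <- mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
    if (sil > bestSil) {
      bestSil <- sil
      best <- km
    }
  }
  if (is.null(best)) {  # degenerate profiles: single cluster
    best <- list(cluster = rep(1L, nrow(v)),
                 centers = matrix(colMeans(v), 1L,
                                  dimnames = list(NULL, colnames(v))))
  }
  best
}

#' Simulate high-precision (ddPCR-like) marker counts
#'
#' Draws binomial variant counts for the panel markers at the assay depth
#' from the tree's blood-sample frequencies, optionally after a Dirichlet
#' drift step on the exclusive clone fractions to emulate longitudinal
#' change (larger \code{driftConcentration} means less drift; \code{Inf}
#' disables it).
#'
#' @param tree a [ClonalTree-class] (must have a \code{blood} sample row,
#'   else the first row is used).
#' @param panel a [MarkerPanel-class].
#' @param depth assay depth per marker.
#' @param seed integer seed.
#' @param driftConcentration Dirichlet concentration of the drift step;
#'   \code{Inf} (default) keeps the fractions fixed.
#' @param timepoint label recorded in the output.
#' @return data.frame with columns \code{marker_id}, \code{variant_reads},
#'   \code{depth}, \code{timepoint}.
#' @export
simulateDdpcr <- function(tree, panel, depth, seed, driftConcentration = Inf,
                          timepoint = "t1") {
  set.seed(.childSeed(seed, "ddpcr"))
  s <- if ("blood" %in% rownames(tree@F)) "blood" else 1L
  phi <- cloneFractions(tree, s)
  if (is.finite(driftConcentration)) {
    a <- driftConcentration * (phi + 1e-9)
    g <- stats::rgamma(length(a), shape = a)
    phi <- g / sum(g) * sum(phi)  # redistribute within the tumor mass
  }
  Fdrift <- .subtreeSums(tree@parent, phi)
  idx <- markerIndices(panel)
  f <- Fdrift[tree@mutClone[idx]]
  data.frame(marker_id = markerIds(panel),
             variant_reads = stats::rbinom(length(idx), depth, f),
             depth = rep(depth, length(idx)),
             timepoint = timepoint,
             stringsAsFactors = FALSE)
}
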