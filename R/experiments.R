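#' Simulate one complete study case
#'
#' Draws a ground-truth tree, simulates bulk reads for every sample, and
#' estimates the bootstrap tree density — the full front end of the marker
#' selection workflow for one synthetic patient.
#'
#' @param config a [simConfig()] list (its \code{seed} drives all stages).
#' @return list with elements \code{truth} ([ClonalTree-class]),
#'   \code{reads} (named list of per-sample read tables), and
#'   \code{density} ([TreeDensity-class]).
#' @export
simulateCase <- function(config) {
  truth <- simulateTree(config)
  samples <- rownames(cloneFrequencies(truth))
  reads <- lapply(samples, function(s) {
    simulateReads(truth, s, config$seqDepth, config$seed)
  })
  names(reads) <- samples
  list(truth = truth, reads = reads,
       density = bootstrapDensity(reads, config))
}

#' Density-refinement study over simulated cases
#'
#' For each seeded case, selects a structure-discriminating panel and an
#' equally sized random panel, simulates high-precision marker counts from
#' the ground truth, Bayesian-updates the bootstrap density with each panel,
#' and records weighted CASet/DISC distances to the truth and the best tree's
#' weight before and after the update.
#'
#' @param nCases number of simulated cases.
#' @param seed master seed; case \code{i} uses \code{seed + i}.
#' @param nMarkers panel size.
#' @param config template [simConfig()]; each case clones it with its own
#'   seed.
#' @param params [structureParams()] for panel selection; the default runs in
#'   the structure-dominant regime (\code{logLambda = 1e4}) at the ddPCR
#'   depth, so selection targets ancestor-structure differences — the signal
#'   the pairwise Bayesian update can exploit.
#' @return data.frame, one row per case, with distances and weights for the
#'   structure-selected and random panels.
#' @export
runRefinementStudy <- function(nCases = 10, seed = 1, nMarkers = 5,
                               config = simConfig(),
                               params = NULL) {
  if (is.null(params)) {
    params <- structureParams(depth = config$ddpcrDepth, logLambda = 1e4)
  }
  rows <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    cs <- simulateCase(cfg)
    dens <- cs$density
    truth <- cs$truth
    N <- nMutations(truth)
    structPanel <- selectStructureMarkers(dens, nMarkers, params)
    set.seed(cfg$seed + 7L)
    randPanel <- MarkerPanel(sort(sample.int(N, nMarkers)),
                             universe = mutationIds(truth))
    densS <- updateWeights(dens, structPanel,
                           simulateDdpcr(truth, structPanel, cfg$ddpcrDepth,
                                         cfg$seed))
    densR <- updateWeights(dens, randPanel,
                           simulateDdpcr(truth, randPanel, cfg$ddpcrDepth,
                                         cfg$seed))
    rows[[i]] <- data.frame(
      case = i,
      nTrees = length(dens),
      caset_before = weightedDistance(dens, truth, "CASet"),
      caset_struct = weightedDistance(densS, truth, "CASet"),
      caset_random = weightedDistance(densR, truth, "CASet"),
      disc_before = weightedDistance(dens, truth, "DISC"),
      disc_struct = weightedDistance(densS, truth, "DISC"),
      disc_random = weightedDistance(densR, truth, "DISC"),
      bestw_before = as.numeric(bestTreeWeight(dens, truth, "CASet")),
      bestw_struct = as.numeric(bestTreeWeight(densS, truth, "CASet")),
      bestw_random = as.numeric(bestTreeWeight(densR, truth, "CASet"))
    )
  }
  do.call(rbind, rows)
}

#' Clone-tracking study over simulated cases
#'
#' For each seeded case and each panel size, selects a tracking-optimized
#' panel on the bootstrap density and draws a random panel, then records the
#' trackable fraction both in expectation over the density (the selection
#' objective) and on the ground-truth tree.
#'
#' @param nCases number of simulated cases.
#' @param seed master seed; case \code{i} uses \code{seed + i}.
#' @param nRange panel sizes to sweep.
#' @param mode information assumption, \code{"partial"} or \code{"complete"}.
#' @param config template [simConfig()].
#' @return data.frame with one row per case and panel size.
#' @export
runTrackingStudy <- function(nCases = 10, seed = 1, nRange = 1:8,
                             mode = "partial", config = simConfig()) {
  rows <- list()
  for (i in seq_len(nCases)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    cs <- simulateCase(cfg)
    dens <- cs$density
    truth <- cs$truth
    N <- nMutations(truth)
    ids <- mutationIds(truth)
    for (n in nRange) {
      optPanel <- selectTrackingMarkers(dens, n, mode = mode)
      set.seed(cfg$seed + 13L + n)
      rndPanel <- MarkerPanel(sort(sample.int(N, n)), universe = ids)
      expFrac <- function(panel) {
        sum(treeWeights(dens) * vapply(trees(dens), function(t) {
          trackableFraction(t, match(markerIds(panel), mutationIds(t)),
                            mode = mode)
        }, numeric(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        case = i, n = n,
        expected_opt = expFrac(optPanel),
        expected_random = expFrac(rndPanel),
        truth_opt = trackableFraction(truth, optPanel, mode = mode),
        truth_random = trackableFraction(truth, rndPanel, mode = mode)
      )
    }
  }
  do.call(rbind, rows)
}
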