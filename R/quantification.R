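#' Estimate per-clone fractions from measured marker VAFs
#'
#' For a chosen tree, the frequency of a clone at each time point is
#' estimated as the mean VAF of its measured markers minus the sum of the
#' mean VAFs of its measured child clones. Clones with unmeasured children
#' are quantified at subtree level (the subtraction skips unmeasured
#' children) and flagged; clones with no measured marker are absent from the
#' output and listed in the \code{"unmeasured"} attribute. Negative estimates
#' - possible when child markers are observed at higher frequency than the
#' parent's, an impossible configuration for exact frequencies but a real
#' occurrence under assay noise or topology error - are retained and flagged,
#' not clipped, unless \code{projectSimplex} is set.
#'
#' @param tree a [ClonalTree-class].
#' @param panel a [MarkerPanel-class] restricted to this tree's mutations.
#' @param counts data.frame with columns \code{marker_id},
#'   \code{variant_reads}, \code{depth}, \code{timepoint} covering every
#'   panel marker at every time point (VAF = variant_reads / depth).
#' @param projectSimplex post-hoc projection of each time point's estimates
#'   onto the nonnegative simplex scale (clip at zero); off by default so
#'   that anomalous negative estimates stay visible.
#' @return data.frame (one row per measured clone and time point) with
#'   columns \code{timepoint}, \code{clone_id}, \code{estimate},
#'   \code{n_markers}, \code{negative}, \code{subtree_level}; attribute
#'   \code{"unmeasured"} lists clone ids with no marker.
#' @export
estimateFractions <- function(tree, panel, counts, projectSimplex = FALSE) {
  ids <- markerIds(panel)
  idx <- .resolveMutations(tree, ids)
  need <- c("marker_id", "variant_reads", "depth", "timepoint")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  cl <- tree@mutClone[idx]
  out <- list()
  for (tp in unique(counts$timepoint)) {
    sub <- counts[counts$timepoint == tp, , drop = FALSE]
    row <- match(ids, sub$marker_id)
    if (anyNA(row)) {
      stop("time point ", tp, " missing counts for marker(s): ",
           paste(ids[is.na(row)], collapse = ", "))
    }
    vaf <- sub$variant_reads[row] / sub$depth[row]
    measured <- sort(unique(cl))
    cloneMean <- vapply(measured, function(i) mean(vaf[cl == i]), numeric(1))
    nm <- vapply(measured, function(i) sum(cl == i), integer(1))
    est <- numeric(length(measured))
    partial <- logical(length(measured))
    for (s in seq_along(measured)) {
      ch <- childrenOf(tree, measured[s])
      chMeasured <- ch[ch %in% measured]
      est[s] <- cloneMean[s] -
        sum(cloneMean[match(chMeasured, measured)])
      partial[s] <- length(chMeasured) < length(ch)
    }
    neg <- est < 0
    if (projectSimplex) est[neg] <- 0
    out[[length(out) + 1L]] <- data.frame(
      timepoint = tp,
      clone_id = cloneIds(tree)[measured],
      estimate = est,
      n_markers = nm,
      negative = neg,
      subtree_level = partial,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "unmeasured") <-
    setdiff(cloneIds(tree), cloneIds(tree)[unique(cl)])
  res
}
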