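.SCHEMA_VERSION <- "1.0"

.checkSchemaVersion <- function(obj, what) {
  v <- obj$schema_version
  if (is.null(v)) return(invisible(NULL))  # tolerate absent field
  major <- as.integer(strsplit(as.character(v), ".", fixed = TRUE)[[1L]][1L])
  ours <- as.integer(strsplit(.SCHEMA_VERSION, ".", fixed = TRUE)[[1L]][1L])
  if (is.na(major) || major > ours) {
    stop(what, ": unsupported schema_version ", v)
  }
  invisible(NULL)
}

.treeToList <- function(tree) {
  list(
    schema_version = .SCHEMA_VERSION,
    clones = lapply(seq_len(nClones(tree)), function(i) {
      list(id = tree@cloneIds[i],
           parent = if (is.na(tree@parent[i])) NULL else
             tree@cloneIds[tree@parent[i]],
           mutations = as.list(tree@mutIds[tree@mutClone == i]))
    }),
    frequencies = stats::setNames(
      lapply(seq_len(nSamples(tree)), function(s) as.list(tree@F[s, ])),
      rownames(tree@F)
    )
  )
}

.treeFromList <- function(obj, what = "tree") {
  .checkSchemaVersion(obj, what)
  clones <- obj$clones
  if (is.null(clones) || !length(clones)) stop(what, ": no clones")
  ids <- vapply(clones, function(cl) {
    if (is.null(cl$id)) stop(what, ": clone without an id")
    as.character(cl$id)
  }, character(1))
  parent <- vapply(seq_along(clones), function(i) {
    cl <- clones[[i]]
    if (!("parent" %in% names(cl))) {
      stop(what, ": clone '", ids[i], "' is missing the parent field")
    }
    p <- cl$parent
    if (is.null(p) || (length(p) == 1L && is.na(p))) return(NA_integer_)
    j <- match(as.character(p), ids)
    if (is.na(j)) stop(what, ": clone '", ids[i], "' has unknown parent '", p, "'")
    j
  }, integer(1))
  mutIds <- character(0)
  mutClone <- integer(0)
  for (i in seq_along(clones)) {
    mm <- unlist(clones[[i]]$mutations)
    if (length(mm)) {
      mutIds <- c(mutIds, as.character(mm))
      mutClone <- c(mutClone, rep(i, length(mm)))
    }
  }
  fr <- obj$frequencies
  if (is.null(fr) || !length(fr)) stop(what, ": missing frequencies")
  Fm <- do.call(rbind, lapply(fr, function(v) {
    v <- as.numeric(unlist(v))
    if (length(v) != length(ids)) {
      stop(what, ": frequency row length does not match clone count")
    }
    v
  }))
  rownames(Fm) <- names(fr)
  ClonalTree(parent, mutClone, Fm, cloneIds = ids, mutIds = mutIds)
}

#' Read and write clonal trees, densities, and panels as JSON
#'
#' The tree schema is
#' \code{\{schema_version, clones: [\{id, parent, mutations\}], frequencies:
#' \{sample: [per-clone subtree-sum values]\}\}}; a density adds
#' \code{trees} and integer \code{counts}; a panel stores \code{markers} as
#' mutation ids. Writing then reading reproduces the structure exactly at the
#' schema level. Readers reject newer schema majors and report violations
#' with the offending clone/field named.
#'
#' @param path file path.
#' @param tree,density,panel the object to write.
#' @name json-io
NULL

#' @rdname json-io
#' @export
readTreeJSON <- function(path) {
  .treeFromList(jsonlite::read_json(path), what = basename(path))
}

#' @rdname json-io
#' @export
writeTreeJSON <- function(tree, path) {
  jsonlite::write_json(.treeToList(tree), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname json-io
#' @export
readDensityJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  .checkSchemaVersion(obj, basename(path))
  if (is.null(obj$trees) || !length(obj$trees)) stop("density: no trees")
  counts <- unlist(obj$counts)
  if (is.null(counts)) counts <- rep(1, length(obj$trees))
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("density: counts must be integers")
  }
  trs <- lapply(seq_along(obj$trees), function(k) {
    .treeFromList(obj$trees[[k]], what = sprintf("density tree %d", k))
  })
  dens <- TreeDensity(trs, counts = as.numeric(counts), deduplicate = FALSE)
  w <- unlist(obj$weights)
  if (!is.null(w)) {   # posterior weights, if stored, override count weights
    if (length(w) != length(trs) || any(w < 0)) {
      stop("density: invalid weights field")
    }
    dens@weights <- w / sum(w)
  }
  dens
}

#' @rdname json-io
#' @export
writeDensityJSON <- function(density, path) {
  obj <- list(schema_version = .SCHEMA_VERSION,
              trees = lapply(trees(density), .treeToList),
              counts = treeCounts(density),
              weights = treeWeights(density))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname json-io
#' @export
readPanelJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  .checkSchemaVersion(obj, basename(path))
  ids <- as.character(unlist(obj$markers))
  if (!length(ids)) stop("panel: no markers")
  new("MarkerPanel", markers = seq_along(ids), ids = ids)
}

#' @rdname json-io
#' @export
writePanelJSON <- function(panel, path) {
  obj <- list(schema_version = .SCHEMA_VERSION,
              markers = markerIds(panel))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a marker read-count table
#'
#' Tab-separated with columns \code{marker_id}, \code{variant_reads},
#' \code{depth}, \code{timepoint}.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readCountsTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "variant_reads", "depth", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("counts TSV missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$variant_reads < 0 | df$variant_reads > df$depth)) {
    stop("counts TSV: variant_reads must lie in [0, depth]")
  }
  df
}

#' @rdname readCountsTSV
#' @param counts data.frame of counts.
#' @export
writeCountsTSV <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a PhyloWGS-style summary into a tree density
#'
#' Accepts a JSON file with a top-level \code{trees} map; each entry carries
#' \code{structure} (parent node -> list of child nodes), \code{populations}
#' (node -> \code{cellular_prevalence}, one value per sample), optional
#' \code{mut_assignments} (node -> \code{ssms} list) and an optional
#' \code{count} multiplicity. Cellular prevalences map directly onto the
#' subtree-sum frequency matrix; nodes without SSMs (e.g. the germline root)
#' are retained as markerless clones and reported in a message.
#'
#' @param path JSON file path.
#' @param sampleNames optional names for the prevalence columns.
#' @return a [TreeDensity-class].
#' @export
readPhyloWGS <- function(path, sampleNames = NULL) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON: ",
                                           conditionMessage(e)))
  if (is.null(obj$trees) || !length(obj$trees)) {
    stop("unsupported format: expected a top-level 'trees' map")
  }
  trs <- list()
  counts <- numeric(0)
  markerless <- character(0)
  for (key in names(obj$trees)) {
    tr <- obj$trees[[key]]
    if (is.null(tr$structure) || is.null(tr$populations)) {
      stop("unsupported format: tree '", key,
           "' lacks structure/populations")
    }
    nodeIds <- unique(c(names(tr$structure),
                        unlist(lapply(tr$structure, unlist)),
                        names(tr$populations)))
    nodeIds <- as.character(sort(as.integer(nodeIds)))
    n <- length(nodeIds)
    parent <- rep(NA_integer_, n)
    for (p in names(tr$structure)) {
      for (ch in unlist(tr$structure[[p]])) {
        parent[match(as.character(ch), nodeIds)] <- match(p, nodeIds)
      }
    }
    mutIds <- character(0)
    mutClone <- integer(0)
    for (i in seq_len(n)) {
      ssms <- unlist(tr$mut_assignments[[nodeIds[i]]]$ssms)
      if (length(ssms)) {
        mutIds <- c(mutIds, as.character(ssms))
        mutClone <- c(mutClone, rep(i, length(ssms)))
      } else {
        markerless <- c(markerless, paste0(key, ":node", nodeIds[i]))
      }
    }
    prev <- lapply(nodeIds, function(id) {
      p <- tr$populations[[id]]$cellular_prevalence
      if (is.null(p)) stop("tree '", key, "' node ", id,
                           " has no cellular_prevalence")
      as.numeric(unlist(p))
    })
    S <- length(prev[[1L]])
    Fm <- do.call(cbind, prev)
    rownames(Fm) <- if (!is.null(sampleNames)) sampleNames else
      paste0("s", seq_len(S))
    trs[[length(trs) + 1L]] <- ClonalTree(
      parent, mutClone, Fm, cloneIds = paste0("node", nodeIds),
      mutIds = mutIds)
    counts <- c(counts, if (is.null(tr$count)) 1 else as.numeric(tr$count))
  }
  if (length(markerless)) {
    message("markerless clone(s) retained: ",
            paste(markerless, collapse = ", "))
  }
  TreeDensity(trs, counts = counts)
}

#' Read candidate mutations from a VCF
#'
#' Extracts per-sample variant and total read counts from the \code{AD}
#' format field. Multiallelic records are split into one mutation per
#' alternate allele; mutation ids are \code{chrom:pos:ref:alt} (1-based
#' coordinates as in the VCF).
#'
#' @param path path to an (uncompressed or gzipped) VCF with an AD field.
#' @return data.frame with columns \code{mutation_id}, \code{sample},
#'   \code{variant_reads}, \code{depth}.
#' @export
readVcfMutations <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCFs requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad) || all(is.na(ad))) {
    stop("VCF has no AD (allelic depth) format field; cannot derive counts")
  }
  fix <- vcfR::getFIX(v)
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    for (s in colnames(ad)) {
      parts <- suppressWarnings(
        as.numeric(strsplit(ad[i, s], ",", fixed = TRUE)[[1L]]))
      if (anyNA(parts)) next
      depth <- sum(parts)
      for (a in seq_along(alts)) {
        out[[length(out) + 1L]] <- data.frame(
          mutation_id = paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"],
                              alts[a], sep = ":"),
          sample = s,
          variant_reads = parts[a + 1L],
          depth = depth,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) stop("no usable AD entries found in VCF")
  do.call(rbind, out)
}
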