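# End-to-end connectivity search: given two nodes, rank all metapaths (up
# to a maximum length) between their metanodes by Bonferroni-adjusted
# DWPC p-value, and rank the individual paths carrying the signal by path
# score = (fraction of the DWPC contributed) * (-log10 of the DWPC's
# p-value).

#' Path degree product
#'
#' The per-path contribution to a DWPC: the product over the path's edges
#' of (source degree)^-w * (target degree)^-w, with metaedge-specific,
#' orientation-correct degrees.  With \code{w = 0} every valid path
#' contributes 1.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param path character vector of node identifiers, one per metapath
#'   position (no duplicate nodes).
#' @param metapath a \linkS4class{Metapath} or abbreviation.
#' @param w damping exponent.
#' @return a single non-negative number.
#' @export
pathDegreeProduct <- function(store, path, metapath, w = 0.5) {
  if (is.character(metapath)) metapath <- .parseMetapath(store@metagraph, metapath)
  types <- .typeSeq(metapath)
  if (length(path) != length(types)) {
    .stopf("hetpath_validation_error", "path has %d nodes but metapath %s needs %d",
           length(path), abbreviation(metapath), length(types))
  }
  idx <- integer(length(path))
  for (k in seq_along(path)) {
    idx[k] <- match(path[k], nodeIds(store, types[k]))
    if (is.na(idx[k])) {
      .stopf("hetpath_validation_error", "node %s is not a %s node", path[k], types[k])
    }
  }
  for (ty in unique(types)) {
    if (anyDuplicated(idx[types == ty])) {
      .stopf("hetpath_validation_error", "path revisits a node; only simple paths are valid")
    }
  }
  pdp <- 1
  for (k in seq_len(length(metapath))) {
    m <- adjacencyMatrix(store, metapath@edges[k], inverted = metapath@inverted[k])
    if (m[idx[k], idx[k + 1L]] == 0) {
      .stopf("hetpath_validation_error", "no %s edge between %s and %s",
             .subAbbrev(metapath, k, k + 1L), path[k], path[k + 1L])
    }
    ds <- Matrix::rowSums(m)[idx[k]]
    dt <- Matrix::colSums(m)[idx[k + 1L]]
    pdp <- pdp * (ds * dt)^(-w)
  }
  unname(pdp)
}

#' Enumerate the simple paths behind one DWPC entry
#'
#' All simple paths of the metapath between the two nodes, each with its
#' path degree product and the fraction of the DWPC it contributes.  The
#' path degree products sum to the (source, target) entry of the DWPC
#' matrix.
#'
#' @inheritParams pathDegreeProduct
#' @param sourceNode,targetNode node identifiers.
#' @param budget maximum number of path extensions.
#' @return data.frame with columns \code{path} (node identifiers joined by
#'   \code{" - "}), \code{pdp}, \code{percent_of_dwpc}, sorted by
#'   \code{pdp} descending.
#' @export
enumeratePaths <- function(store, sourceNode, targetNode, metapath, w = 0.5,
                           budget = 1e7) {
  if (is.character(metapath)) metapath <- .parseMetapath(store@metagraph, metapath)
  types <- .typeSeq(metapath)
  L <- length(metapath)
  src <- match(sourceNode, nodeIds(store, types[1L]))
  tgt <- match(targetNode, nodeIds(store, types[L + 1L]))
  if (is.na(src) || is.na(tgt)) {
    .stopf("hetpath_validation_error", "source/target node not found for metapath %s",
           abbreviation(metapath))
  }
  mats <- lapply(seq_len(L), function(k) {
    dampedAdjacency(store, metapath@edges[k], w = w, inverted = metapath@inverted[k])
  })
  adjList <- lapply(mats, function(m) {
    tm <- methods::as(Matrix::t(m), "CsparseMatrix")
    list(p = tm@p, j = tm@i + 1L, x = tm@x)
  })
  paths <- list()
  pdps <- numeric()
  used <- 0
  nodesSeq <- integer(L + 1L)
  rec <- function(pos, node, wgt) {
    nodesSeq[pos] <<- node
    if (pos == L + 1L) {
      if (node == tgt) {
        paths[[length(paths) + 1L]] <<- nodesSeq
        pdps[[length(pdps) + 1L]] <<- wgt
      }
      return(invisible())
    }
    al <- adjList[[pos]]
    lo <- al$p[node] + 1L; hi <- al$p[node + 1L]
    if (hi < lo) return(invisible())
    for (e in lo:hi) {
      used <<- used + 1
      if (used > budget) {
        .stopf("hetpath_budget_error",
               "path enumeration budget exceeded (budget = %.0f extensions)", budget)
      }
      nxt <- al$j[e]
      # reject revisits of a node within the same metanode
      dup <- FALSE
      for (q in seq_len(pos)) {
        if (types[q] == types[pos + 1L] && nodesSeq[q] == nxt) { dup <- TRUE; break }
      }
      if (!dup) rec(pos + 1L, nxt, wgt * al$x[e])
    }
    invisible()
  }
  rec(1L, src, 1)
  if (!length(paths)) {
    return(data.frame(path = character(), pdp = numeric(),
                      percent_of_dwpc = numeric(), stringsAsFactors = FALSE))
  }
  labels <- vapply(paths, function(pp) {
    paste(vapply(seq_along(pp), function(k) nodeIds(store, types[k])[pp[k]],
                 character(1)), collapse = " - ")
  }, character(1))
  pdp <- unlist(pdps)
  out <- data.frame(path = labels, pdp = pdp,
                    percent_of_dwpc = pdp / sum(pdp), stringsAsFactors = FALSE)
  out <- out[order(-out$pdp, out$path), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Path score
#'
#' Ranks paths across metapaths: the fraction of its metapath's DWPC a
#' path contributes, times the magnitude \eqn{-\log_{10} p} of the DWPC's
#' p-value.  An empirical p-value of exactly 0 is capped at
#' \eqn{-\log_{10} p = } \code{cap} to keep scores finite.
#'
#' @param percentOfDwpc fraction in [0, 1].
#' @param p the metapath DWPC p-value.
#' @param cap cap on \eqn{-\log_{10} p} (default 320, around the smallest
#'   representable double).
#' @return a non-negative number.
#' @export
pathScore <- function(percentOfDwpc, p, cap = 320) {
  if (any(percentOfDwpc < 0 | percentOfDwpc > 1)) {
    .stopf("hetpath_validation_error", "percentOfDwpc must be in [0, 1]")
  }
  if (any(p < 0 | p > 1)) .stopf("hetpath_validation_error", "p must be in [0, 1]")
  percentOfDwpc * pmin(-log10(p), cap)
}

#' Database-storage threshold for enriched metapaths
#'
#' The adjusted p-value cutoff under which a (node pair, metapath) row is
#' worth persisting: length-1 metapaths store all nonzero DWPCs (returned
#' as \code{Inf}, i.e. no p-value cutoff), longer metapaths use
#' \eqn{5 (n_{source} n_{target})^{-0.3}}, penalizing metapaths with many
#' possible node pairs.
#'
#' @param nSource,nTarget node counts of the source and target metanodes.
#' @param length metapath length.
#' @return the threshold (\code{Inf} means "store all nonzero DWPCs").
#' @export
storageThreshold <- function(nSource, nTarget, length) {
  stopifnot(nSource >= 1, nTarget >= 1)
  if (length == 1L) return(Inf)
  5 * (as.numeric(nSource) * as.numeric(nTarget))^(-0.3)
}

# stats lookup keyed by (metapath, ds, dt); NULL when the group is absent
.lookupStats <- function(nulls, mpAbbrev, ds, dt) {
  hit <- nulls[nulls$metapath == mpAbbrev &
                 nulls$source_degree == ds & nulls$target_degree == dt, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit[1L, ]
}

#' Connectivity search between two nodes
#'
#' For every metapath of length <= \code{maxLength} between the metanodes
#' of \code{nodeA} and \code{nodeB} (each metapath counted once; reversed
#' orientations are resolved via the transpose), computes the path count,
#' DWPC, gamma-hurdle/empirical p-value against the degree-grouped null,
#' and the Bonferroni-adjusted p-value.  Metapath rows are sorted by
#' adjusted p-value (ties: DWPC descending, then abbreviation); the simple
#' paths of the reported metapaths are pooled and sorted by path score.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param nulls degree-grouped null statistics from
#'   \code{\link{computeNullStats}} covering the relevant metapaths.
#' @param nodeA,nodeB node identifiers (any metanode).
#' @param maxLength maximum metapath length (default 3).
#' @param w damping exponent (must match the one used for \code{nulls}).
#' @param applyStorageFilter keep only metapath rows passing
#'   \code{\link{storageThreshold}} (and, for the path table, only paths of
#'   kept metapaths).
#' @param pathScoreAdjusted use the adjusted instead of the raw p-value in
#'   path scores.
#' @param enumerateBudget path-enumeration budget per metapath.
#' @return list with data.frames \code{metapaths} (columns \code{metapath},
#'   \code{path_count}, \code{dwpc}, \code{p_value},
#'   \code{adjusted_p_value}, \code{source_degree}, \code{target_degree},
#'   \code{n_dwpcs}, \code{n_nonzero_dwpcs}, \code{nonzero_mean},
#'   \code{nonzero_sd}) and \code{paths} (columns \code{path},
#'   \code{metapath}, \code{path_score}, \code{percent_of_dwpc},
#'   \code{pdp}).
#' @export
connectivitySearch <- function(store, nulls, nodeA, nodeB, maxLength = 3,
                               w = 0.5, applyStorageFilter = FALSE,
                               pathScoreAdjusted = FALSE,
                               enumerateBudget = 1e7) {
  mg <- store@metagraph
  locate <- function(id) {
    for (mn in mg@metanodes$abbreviation) {
      if (id %in% nodeIds(store, mn)) return(mn)
    }
    all <- unlist(lapply(mg@metanodes$abbreviation, function(mn) nodeIds(store, mn)))
    near <- agrep(id, all, max.distance = 0.3, value = TRUE)
    .stopf("hetpath_lookup_error", "unknown node identifier '%s'%s", id,
           if (length(near)) paste0("; did you mean: ",
                                    paste(head(near, 5L), collapse = ", "), "?") else "")
  }
  mnA <- locate(nodeA)
  mnB <- locate(nodeB)
  cand <- .enumerateDf(mg, maxLength)
  cand <- cand[(cand$source == mnA & cand$target == mnB) |
                 (cand$source == mnB & cand$target == mnA), , drop = FALSE]
  rowsM <- list()
  rowsP <- list()
  for (r in seq_len(nrow(cand))) {
    mp <- .parseMetapath(mg, cand$abbreviation[r])
    # orient so the metapath runs nodeA -> nodeB
    if (sourceMetanode(mp) != mnA || targetMetanode(mp) != mnB) mp <- reverse(mp)
    ab <- abbreviation(mp)
    canonical <- cand$abbreviation[r]   # nulls are keyed by this orientation
    dmat <- dwpcMatrix(dwpc(store, mp, w = w))
    pmat <- dwpcMatrix(dwpc(store, mp, w = 0))
    t0 <- dmat[nodeA, nodeB]
    pc <- pmat[nodeA, nodeB]
    key <- degreeGroupKey(store, mp, nodeA, nodeB)
    # stats were accumulated in the canonical orientation
    if (ab == canonical) {
      st <- .lookupStats(nulls, canonical, key[1L], key[2L])
    } else {
      st <- .lookupStats(nulls, canonical, key[2L], key[1L])
    }
    if (is.null(st)) {
      .stopf("hetpath_validation_error",
             "no null statistics for metapath %s, degree group (%g, %g)",
             canonical, key[1L], key[2L])
    }
    sig <- dwpcPvalue(t0, stats = st)
    adj <- bonferroniAdjust(sig$p_value, mg, mnA, mnB, length(mp))
    rowsM[[length(rowsM) + 1L]] <- data.frame(
      metapath = ab, path_count = pc, dwpc = t0,
      p_value = sig$p_value, adjusted_p_value = adj,
      source_degree = unname(key[1L]), target_degree = unname(key[2L]),
      n_dwpcs = st$n_dwpcs, n_nonzero_dwpcs = st$n_nonzero_dwpcs,
      nonzero_mean = sig$nonzero_mean, nonzero_sd = sig$nonzero_sd,
      stringsAsFactors = FALSE)
    keep <- !applyStorageFilter ||
      (t0 > 0 && adj <= storageThreshold(nrow(store@nodes[[mnA]]),
                                         nrow(store@nodes[[mnB]]), length(mp)))
    if (keep && t0 > 0) {
      pp <- enumeratePaths(store, nodeA, nodeB, mp, w = w, budget = enumerateBudget)
      pUse <- if (pathScoreAdjusted) adj else sig$p_value
      pp$metapath <- ab
      pp$path_score <- pathScore(pp$percent_of_dwpc, pUse)
      rowsP[[length(rowsP) + 1L]] <- pp[, c("path", "metapath", "path_score",
                                            "percent_of_dwpc", "pdp")]
    }
  }
  mtab <- if (length(rowsM)) do.call(rbind, rowsM) else
    data.frame(metapath = character(), path_count = numeric(), dwpc = numeric(),
               p_value = numeric(), adjusted_p_value = numeric(),
               source_degree = numeric(), target_degree = numeric(),
               n_dwpcs = numeric(), n_nonzero_dwpcs = numeric(),
               nonzero_mean = numeric(), nonzero_sd = numeric(),
               stringsAsFactors = FALSE)
  if (applyStorageFilter && nrow(mtab)) {
    thr <- vapply(mtab$metapath, function(a) {
      storageThreshold(nrow(store@nodes[[mnA]]), nrow(store@nodes[[mnB]]),
                       length(.parseMetapath(mg, a)))
    }, numeric(1))
    mtab <- mtab[mtab$dwpc > 0 & mtab$adjusted_p_value <= thr, , drop = FALSE]
  }
  ord <- order(mtab$adjusted_p_value, -mtab$dwpc, mtab$metapath)
  mtab <- mtab[ord, , drop = FALSE]
  rownames(mtab) <- NULL
  ptab <- if (length(rowsP)) do.call(rbind, rowsP) else
    data.frame(path = character(), metapath = character(), path_score = numeric(),
               percent_of_dwpc = numeric(), pdp = numeric(), stringsAsFactors = FALSE)
  ptab <- ptab[order(-ptab$path_score, ptab$path), , drop = FALSE]
  rownames(ptab) <- NULL
  list(metapaths = mtab, paths = ptab)
}
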