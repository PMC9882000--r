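# Degree-preserving permutation of hetnets via XSwap.
#
# XSwap repeatedly picks two edges (a,b), (c,d) and swaps their endpoints
# to (a,d), (c,b); a swap is rejected if it would create a self-loop or a
# duplicate edge.  Every accepted swap preserves each node's degree
# exactly, so the permuted network retains degree structure while the
# meaning of individual edges is destroyed.  Applied independently to each
# metaedge of a hetnet.

#' XSwap an edge list
#'
#' @param edges two-column integer matrix of (source, target) node
#'   positions, free of self-loops and duplicates.  For undirected
#'   same-metanode edge sets, pass each unordered pair once (any order).
#' @param multiplier swap attempts per edge; total attempts =
#'   \code{round(multiplier * nrow(edges))}.
#' @param seed integer seed for the swap stream (the caller's RNG state is
#'   left untouched).
#' @param undirected treat edges as unordered pairs over a single node set
#'   (self-loops forbidden, (a,b) and (b,a) are the same edge).
#' @return list with \code{edges} (same shape, canonicalized so
#'   \code{source < target} when \code{undirected}), \code{attempted} and
#'   \code{accepted} swap counts.
#' @export
xswapEdges <- function(edges, multiplier = 10, seed = 0L, undirected = FALSE) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) .stopf("hetpath_validation_error", "edges must have two columns")
  if (!is.numeric(multiplier) || multiplier <= 0) {
    .stopf("hetpath_validation_error", "multiplier must be positive")
  }
  src <- as.integer(edges[, 1L])
  tgt <- as.integer(edges[, 2L])
  if (undirected && any(src == tgt)) {
    .stopf("hetpath_validation_error", "self-loops are not allowed")
  }
  # duplicate bookkeeping: unordered pair keys for undirected edge sets
  key <- if (undirected) {
    function(a, b) paste0(pmin(a, b), ":", pmax(a, b))
  } else {
    function(a, b) paste0(a, ":", b)
  }
  seen <- new.env(parent = emptyenv(), size = length(src) * 2L)
  for (k in key(src, tgt)) {
    if (!is.null(seen[[k]])) .stopf("hetpath_validation_error", "duplicate edge in input")
    seen[[k]] <- TRUE
  }
  m <- length(src)
  attempts <- round(multiplier * m)
  accepted <- 0L
  if (m >= 2L) {
    .withSeed(seed, {
      for (it in seq_len(attempts)) {
        pick <- sample.int(m, 2L)
        e1 <- pick[1L]; e2 <- pick[2L]
        a <- src[e1]; b <- tgt[e1]
        c_ <- src[e2]; d <- tgt[e2]
        # proposed new edges: (a, d) and (c_, b); stored orientation is
        # preserved so the swap rule matches the classic XSwap exactly
        if (a == d || c_ == b) next
        k1 <- key(a, d); k2 <- key(c_, b)
        if (k1 == k2 || !is.null(seen[[k1]]) || !is.null(seen[[k2]])) next
        rm(list = c(key(a, b), key(c_, d)), envir = seen)
        seen[[k1]] <- TRUE; seen[[k2]] <- TRUE
        tgt[e1] <- d
        tgt[e2] <- b
        accepted <- accepted + 1L
      }
    })
  }
  if (undirected) {
    s2 <- pmin(src, tgt); t2 <- pmax(src, tgt)
    src <- s2; tgt <- t2
  }
  list(edges = cbind(source = src, target = tgt),
       attempted = attempts, accepted = accepted)
}

#' Permute a hetnet with XSwap
#'
#' Each metaedge is permuted independently; the swap stream seed for a
#' metaedge is derived deterministically from \code{(seed, metaedge
#' abbreviation)}, so adding a metaedge does not reshuffle the others.
#' Per-node, per-metaedge degrees are preserved exactly; undirected
#' same-metanode matrices stay symmetric with a zero diagonal.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param seed integer seed.
#' @param multiplier swap attempts per edge (default 10).
#' @return a \linkS4class{PermutedHetnet}.
#' @export
permuteHetnet <- function(store, seed = 0L, multiplier = 10) {
  mg <- store@metagraph
  me <- mg@metaedges
  full <- if (nrow(me)) metaedgeAbbrev(me) else character()
  adj <- list()
  stats <- data.frame(metaedge = character(), attempted = integer(),
                      accepted = integer(), stringsAsFactors = FALSE)
  for (k in seq_along(full)) {
    ab <- full[k]
    undirSelf <- me$source[k] == me$target[k] && !me$directed[k]
    el <- edgeList(store, k)
    nSrc <- nrow(store@nodes[[me$source[k]]])
    nTgt <- nrow(store@nodes[[me$target[k]]])
    if (nrow(el) == 0L) {
      adj[[ab]] <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                        dims = c(nSrc, nTgt))
      stats <- rbind(stats, data.frame(metaedge = ab, attempted = 0L, accepted = 0L))
      next
    }
    res <- xswapEdges(el, multiplier = multiplier,
                      seed = .deriveSeed(seed, ab), undirected = undirSelf)
    i <- res$edges[, 1L]; j <- res$edges[, 2L]
    if (undirSelf) { i2 <- c(i, j); j2 <- c(j, i); i <- i2; j <- j2 }
    adj[[ab]] <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nSrc, nTgt))
    stats <- rbind(stats, data.frame(metaedge = ab, attempted = res$attempted,
                                     accepted = res$accepted))
  }
  base <- hetnet(mg, store@nodes, adj)
  new("PermutedHetnet", base, baseFingerprint = hetnetFingerprint(store),
      seed = as.integer(seed), multiplier = multiplier, swapStats = stats)
}

#' Generate a sequence of permuted hetnets
#'
#' Permutation \code{i} uses seed \code{baseSeed + i - 1}.  With a
#' \code{callback} the permutations are streamed (nothing retained);
#' otherwise a list is returned.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param count number of permuted hetnets (>= 1).
#' @param baseSeed integer seed for the first permutation.
#' @param multiplier swap attempts per edge.
#' @param callback optional \code{function(permutedStore, index)} consumer.
#' @return list of \linkS4class{PermutedHetnet} (invisibly \code{NULL} when
#'   streaming via \code{callback}).
#' @export
generatePermutations <- function(store, count, baseSeed = 0L, multiplier = 10,
                                 callback = NULL) {
  stopifnot(count >= 1)
  if (is.null(callback)) {
    return(lapply(seq_len(count), function(i) {
      permuteHetnet(store, seed = baseSeed + i - 1L, multiplier = multiplier)
    }))
  }
  for (i in seq_len(count)) {
    callback(permuteHetnet(store, seed = baseSeed + i - 1L, multiplier = multiplier), i)
  }
  invisible(NULL)
}
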