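# Repeat-pattern analysis of metapaths.
#
# Matrix multiplication counts walks; to count only simple paths the
# computation must correct for repeated metanodes.  A metapath is analysed
# into a tree of segments whose leaves are computable pieces:
#   chain       no repeated metanode; plain matrix product
#   diag        an outer two-occurrence repeat (or a 3-occurrence short
#               repeat); product of children minus its diagonal
#   overlap     interleaved BABA repeats; four-term inclusion-exclusion
#   complex     not segmentable by the above; exact DWPC by enumeration
# Positions are 1-based indices into the metanode sequence (length + 1).

# occurrence positions of every metanode repeated within [i, j]
.repOcc <- function(types, i, j) {
  pos <- i:j
  occ <- split(pos, types[pos])
  occ[lengths(occ) >= 2L]
}

# maximal groups of overlapping repeat intervals within [i, j]
.repeatGroups <- function(occ) {
  if (!length(occ)) return(list())
  iv <- t(vapply(occ, range, numeric(2)))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  groups <- list()
  lo <- iv[1L, 1L]; hi <- iv[1L, 2L]
  for (k in seq_len(nrow(iv))[-1L]) {
    if (iv[k, 1L] < hi) {
      hi <- max(hi, iv[k, 2L])
    } else {
      groups[[length(groups) + 1L]] <- c(lo, hi)
      lo <- iv[k, 1L]; hi <- iv[k, 2L]
    }
  }
  groups[[length(groups) + 1L]] <- c(lo, hi)
  groups
}

# are all occurrence positions of every type in `occ` (except `skip`)
# strictly inside one of the intervals?
.confined <- function(occ, skip, intervals) {
  for (ty in setdiff(names(occ), skip)) {
    p <- occ[[ty]]
    ok <- any(vapply(intervals, function(iv) all(p > iv[1L] & p < iv[2L]), logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

.planNode <- function(kind, pattern, range, children = NULL) {
  list(kind = kind, pattern = pattern, range = range, children = children)
}

# walk [i, j] splitting into repeat groups (recursed) and repeat-free gaps
.planPieces <- function(types, i, j, groups) {
  children <- list()
  pos <- i
  for (g in groups) {
    if (g[1L] > pos) {
      children[[length(children) + 1L]] <-
        .planNode("chain", "no-repeats", c(pos, g[1L]))
    }
    children[[length(children) + 1L]] <- .segmentPlan(types, g[1L], g[2L])
    pos <- g[2L]
  }
  if (pos < j) {
    children[[length(children) + 1L]] <- .planNode("chain", "no-repeats", c(pos, j))
  }
  children
}

# segmentation plan for metanode-type sequence positions i..j
.segmentPlan <- function(types, i, j) {
  occ <- .repOcc(types, i, j)
  if (!length(occ)) return(.planNode("chain", "no-repeats", c(i, j)))
  groups <- .repeatGroups(occ)
  if (length(groups) > 1L || groups[[1L]][1L] != i || groups[[1L]][2L] != j) {
    pat <- if (length(groups) > 1L) "disjoint-groups" else "mixed"
    return(.planNode("product", pat, c(i, j), .planPieces(types, i, j, groups)))
  }
  # a single repeat group spanning the whole range
  tA <- types[i]; tB <- types[j]
  occA <- occ[[tA]]
  if (tA == tB && length(occA) == 2L) {
    # outer pair X...X; correct inner repeats first, then subtract diagonal
    inner <- occ[names(occ) != tA]
    innerGroups <- .repeatGroups(inner)
    children <- .planPieces(types, i, j, innerGroups)
    pat <- if (length(inner)) "nested" else "short-repeat"
    return(.planNode("diag", pat, c(i, j), children))
  }
  if (tA == tB && length(occA) == 3L) {
    m <- occA[2L]
    if (.confined(occ, tA, list(c(i, m), c(m, j)))) {
      children <- list(.segmentPlan(types, i, m), .segmentPlan(types, m, j))
      return(.planNode("diag", "short-repeat", c(i, j), children))
    }
    return(.planNode("complex", "complex", c(i, j)))
  }
  if (tA != tB && length(occA) == 2L && length(occ[[tB]]) == 2L) {
    x2 <- occA[2L]; y1 <- occ[[tB]][1L]
    if (i < y1 && y1 < x2 && x2 < j &&
        .confined(occ, c(tA, tB), list(c(i, y1), c(y1, x2), c(x2, j)))) {
      children <- list(.segmentPlan(types, i, y1),
                       .segmentPlan(types, y1, x2),
                       .segmentPlan(types, x2, j))
      return(.planNode("overlap", "overlapping", c(i, j), children))
    }
  }
  .planNode("complex", "complex", c(i, j))
}

.planHasComplex <- function(node) {
  if (node$kind == "complex") return(TRUE)
  any(vapply(node$children %||% list(), .planHasComplex, logical(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# category of a metanode-type sequence
.categorizeTypes <- function(types) {
  occ <- .repOcc(types, 1L, length(types))
  if (!length(occ)) return("no-repeats")
  plan <- .segmentPlan(types, 1L, length(types))
  if (.planHasComplex(plan)) return("complex")
  groups <- .repeatGroups(occ)
  if (length(groups) > 1L) return("disjoint-groups")
  # single group: find its plan node pattern
  node <- plan
  while (node$kind == "product") {
    hit <- NULL
    for (ch in node$children) if (ch$pattern != "no-repeats") hit <- ch
    node <- hit
  }
  node$pattern
}

#' Classify the repeated-metanode pattern of a metapath
#'
#' Metanodes occurring once need no correction and are ignored.  Categories:
#' \code{"no-repeats"}, \code{"short-repeat"} (a single metanode repeated 2
#' or 3 times, as in \code{GiGdG}), \code{"nested"} (BAAB, as in
#' \code{CtDrDtC}), \code{"overlapping"} (BABA, as in \code{CtDtCtD}),
#' \code{"disjoint-groups"} (independent repeat groups, as in
#' \code{DrDtCrC}), and \code{"complex"} (4+ occurrences or interleavings
#' such as ABCABC, which require path enumeration).
#'
#' @param mp a \linkS4class{Metapath}.
#' @return a character scalar; invariant under metapath reversal.
#' @export
categorizeMetapath <- function(mp) {
  stopifnot(is(mp, "Metapath"))
  .categorizeTypes(.typeSeq(mp))
}

# abbreviation of the sub-metapath covering node positions a..b
.subAbbrev <- function(mp, a, b) {
  me <- mp@metagraph@metaedges
  tys <- .typeSeq(mp)
  steps <- a:(b - 1L)
  toks <- .stepToken(me, mp@edges[steps], mp@inverted[steps])
  paste0(tys[a], paste0(toks, tys[steps + 1L], collapse = ""))
}

#' Segment a metapath by its repeat pattern
#'
#' Produces the hierarchical segmentation used to compute DWPCs: a tree
#' whose leaves are repeat-free chains or complex (enumeration) segments,
#' and whose interior nodes record the correction applied (diagonal
#' subtraction for short/nested repeats, inclusion-exclusion for
#' overlapping repeats).  Leaf segments, in order, concatenate to the
#' metapath (adjacent segments share their boundary metanode).
#'
#' @param mp a \linkS4class{Metapath}.
#' @return a nested list; each node has \code{pattern}, \code{abbreviation},
#'   \code{range} (1-based node positions) and \code{children}.
#' @export
segmentMetapath <- function(mp) {
  stopifnot(is(mp, "Metapath"))
  types <- .typeSeq(mp)
  decorate <- function(node) {
    out <- list(pattern = node$pattern,
                abbreviation = .subAbbrev(mp, node$range[1L], node$range[2L]),
                range = node$range)
    out$children <- lapply(node$children %||% list(), decorate)
    out
  }
  decorate(.segmentPlan(types, 1L, length(types)))
}

#' @rdname segmentMetapath
#' @param seg a segmentation tree from \code{segmentMetapath}.
#' @return \code{segmentLeaves} returns a data.frame of the leaf segments
#'   (columns \code{abbreviation}, \code{pattern}, \code{start}, \code{end}).
#' @export
segmentLeaves <- function(seg) {
  if (!length(seg$children)) {
    return(data.frame(abbreviation = seg$abbreviation, pattern = seg$pattern,
                      start = seg$range[1L], end = seg$range[2L],
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seg$children, segmentLeaves))
}
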