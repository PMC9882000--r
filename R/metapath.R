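#' Metapath: a typed path template
#'
#' A metapath is a composable sequence of metaedges, each traversed in a
#' forward or inverted orientation, e.g. Compound-binds-Gene-participates-
#' Pathway (\code{"CbGpPW"}).  DWPCs are computed per metapath; the metapath
#' abbreviation concatenates metanode and metaedge abbreviations, with
#' \code{">"}/\code{"<"} marking the traversal direction of directed
#' metaedges (e.g. \code{"Gr>G"} and its reverse \code{"G<rG"}).
#'
#' @slot metagraph the \linkS4class{Metagraph} the metapath is defined over.
#' @slot edges integer vector of row indices into the metagraph's metaedge table.
#' @slot inverted logical vector, one flag per step; \code{TRUE} means the
#'   metaedge is traversed target-to-source.
#' @exportClass Metapath
setClass("Metapath", slots = c(metagraph = "Metagraph", edges = "integer",
                               inverted = "logical"))

setValidity("Metapath", function(object) {
  if (length(object@edges) < 1L) return("a metapath has at least one step")
  if (length(object@edges) != length(object@inverted)) {
    return("edges and inverted must have equal length")
  }
  me <- object@metagraph@metaedges
  if (any(object@edges < 1L | object@edges > nrow(me))) {
    return("edge index out of range")
  }
  from <- ifelse(object@inverted, me$target[object@edges], me$source[object@edges])
  to <- ifelse(object@inverted, me$source[object@edges], me$target[object@edges])
  k <- length(object@edges)
  if (k > 1L && any(to[-k] != from[-1L])) {
    return("consecutive metaedges are not composable")
  }
  # undirected same-metanode steps are canonically non-inverted
  undirSelf <- !me$directed[object@edges] & me$source[object@edges] == me$target[object@edges]
  if (any(undirSelf & object@inverted)) {
    return("undirected same-metanode steps must not be inverted")
  }
  TRUE
})

# per-step abbreviation token, honoring orientation of directed metaedges
.stepToken <- function(me, edges, inverted) {
  ab <- me$abbreviation[edges]
  dir <- me$directed[edges]
  ifelse(!dir, ab, ifelse(inverted, paste0("<", ab), paste0(ab, ">")))
}

# metanode abbreviation sequence along a metapath, length(steps) + 1
.typeSeq <- function(mp) {
  me <- mp@metagraph@metaedges
  from <- ifelse(mp@inverted, me$target[mp@edges], me$source[mp@edges])
  to <- ifelse(mp@inverted, me$source[mp@edges], me$target[mp@edges])
  c(from[1L], to)
}

#' @describeIn metapath Number of steps (metaedges) in the metapath.
#' @export
setMethod("length", "Metapath", function(x) length(x@edges))

#' @export
setGeneric("abbreviation", function(x) standardGeneric("abbreviation"))

#' @describeIn metapath The concatenated abbreviation, e.g. \code{"CbGpPWpG"}.
#' @export
setMethod("abbreviation", "Metapath", function(x) {
  me <- x@metagraph@metaedges
  tys <- .typeSeq(x)
  toks <- .stepToken(me, x@edges, x@inverted)
  paste0(tys[1L], paste0(toks, tys[-1L], collapse = ""))
})

#' @export
setGeneric("nodeTypeSequence", function(x) standardGeneric("nodeTypeSequence"))

#' @describeIn metapath Metanode abbreviation at each position (length + 1 values).
#' @export
setMethod("nodeTypeSequence", "Metapath", function(x) .typeSeq(x))

#' @export
setGeneric("sourceMetanode", function(x) standardGeneric("sourceMetanode"))
#' @export
setGeneric("targetMetanode", function(x) standardGeneric("targetMetanode"))

#' @describeIn metapath Metanode abbreviation of the first position.
#' @export
setMethod("sourceMetanode", "Metapath", function(x) .typeSeq(x)[1L])

#' @describeIn metapath Metanode abbreviation of the last position.
#' @export
setMethod("targetMetanode", "Metapath", function(x) tail(.typeSeq(x), 1L))

setMethod("show", "Metapath", function(object) {
  cat(sprintf("Metapath %s (length %d)\n", abbreviation(object), length(object)))
})

#' Reverse a metapath
#'
#' Reverses step order and per-step orientation, so e.g. \code{"GpPWpGaD"}
#' becomes \code{"DaGpPWpG"}.  \code{reverse(reverse(m))} is \code{m}.
#'
#' @param x a \linkS4class{Metapath}.
#' @return the reversed \linkS4class{Metapath}.
#' @export
setGeneric("reverse", function(x, ...) standardGeneric("reverse"))

#' @rdname reverse
#' @param ... ignored.
#' @export
setMethod("reverse", "Metapath", function(x, ...) {
  me <- x@metagraph@metaedges
  edges <- rev(x@edges)
  inverted <- rev(!x@inverted)
  # undirected same-metanode steps stay canonical (orientation is meaningless)
  undirSelf <- !me$directed[edges] & me$source[edges] == me$target[edges]
  inverted[undirSelf] <- FALSE
  new("Metapath", metagraph = x@metagraph, edges = edges, inverted = inverted)
})

# C-locale string comparison: TRUE if a <= b byte-wise
.clexLe <- function(a, b) {
  ai <- utf8ToInt(a)
  bi <- utf8ToInt(b)
  n <- min(length(ai), length(bi))
  if (n > 0L) {
    d <- which(ai[seq_len(n)] != bi[seq_len(n)])
    if (length(d)) return(ai[d[1L]] < bi[d[1L]])
  }
  length(ai) <= length(bi)
}

#' Parse a metapath abbreviation
#'
#' @param mg a \linkS4class{Metagraph}.
#' @param abbrev a metapath abbreviation such as \code{"CbGpPWpG"}.
#' @return a \linkS4class{Metapath}.
#' @examples
#' mg <- toyT2()@metagraph
#' mp <- metapath(mg, "CbG")
#' @export
metapath <- function(mg, abbrev) {
  stopifnot(is(mg, "Metagraph"), is.character(abbrev), length(abbrev) == 1L)
  me <- mg@metaedges
  mnAb <- mg@metanodes$abbreviation
  mnAb <- mnAb[order(-nchar(mnAb))]
  matchMn <- function(s) {
    for (a in mnAb) if (startsWith(s, a)) return(a)
    NULL
  }
  cur <- matchMn(abbrev)
  if (is.null(cur)) .stopf("hetpath_parse_error", "cannot parse metapath '%s': no metanode at start", abbrev)
  rest <- substring(abbrev, nchar(cur) + 1L)
  edges <- integer()
  inverted <- logical()
  while (nzchar(rest)) {
    # candidate steps leaving metanode `cur`
    cand <- which(me$source == cur | me$target == cur)
    hit <- NULL
    for (i in cand) {
      for (inv in c(FALSE, TRUE)) {
        if (inv && !me$directed[i] && me$source[i] == me$target[i]) next
        from <- if (inv) me$target[i] else me$source[i]
        if (from != cur) next
        to <- if (inv) me$source[i] else me$target[i]
        piece <- paste0(.stepToken(me, i, inv), to)
        if (startsWith(rest, piece)) {
          if (is.null(hit) || nchar(piece) > nchar(hit$piece)) {
            hit <- list(i = i, inv = inv, to = to, piece = piece)
          }
        }
      }
    }
    if (is.null(hit)) {
      .stopf("hetpath_parse_error", "cannot parse metapath '%s' at '...%s'", abbrev, rest)
    }
    edges <- c(edges, hit$i)
    inverted <- c(inverted, hit$inv)
    cur <- hit$to
    rest <- substring(rest, nchar(hit$piece) + 1L)
  }
  if (!length(edges)) .stopf("hetpath_parse_error", "metapath '%s' has no steps", abbrev)
  new("Metapath", metagraph = mg, edges = edges, inverted = inverted)
}

# internal alias; lets functions with a `metapath` argument call the parser
.parseMetapath <- function(mg, abbrev) metapath(mg, abbrev)

# step table used by enumeration: one row per traversable (metaedge,
# orientation).  Undirected same-metanode metaedges contribute a single
# orientation; everything else contributes both where composable.
.stepTable <- function(mg) {
  me <- mg@metaedges
  n <- nrow(me)
  if (n == 0L) {
    return(data.frame(edge = integer(), inverted = logical(),
                      from = character(), to = character()))
  }
  fwd <- data.frame(edge = seq_len(n), inverted = FALSE,
                    from = me$source, to = me$target)
  invOk <- !(me$source == me$target & !me$directed)
  bwd <- data.frame(edge = which(invOk), inverted = rep(TRUE, sum(invOk)),
                    from = me$target[invOk], to = me$source[invOk])
  rbind(fwd, bwd)
}

#' Enumerate metapaths over a metagraph
#'
#' All composable metaedge sequences of length 1 to \code{maxLength}.  A
#' metapath and its reverse describe the same connectivity, so only one
#' orientation is kept: the one whose abbreviation is lexicographically
#' smaller (byte order); palindromic metapaths are their own reverse.
#'
#' @param mg a \linkS4class{Metagraph}.
#' @param maxLength maximum number of steps (\code{0} gives an empty result).
#' @param as return a list of \linkS4class{Metapath} objects or a summary
#'   data.frame with columns \code{abbreviation}, \code{length},
#'   \code{source}, \code{target}, \code{category}.
#' @return list of metapaths (named by abbreviation) or a data.frame.
#' @export
enumerateMetapaths <- function(mg, maxLength, as = c("list", "data.frame")) {
  as <- match.arg(as)
  df <- .enumerateDf(mg, maxLength)
  if (as == "data.frame") {
    df$category <- vapply(df$types, .categorizeTypes, character(1))
    df$types <- NULL
    return(df)
  }
  mps <- lapply(df$abbreviation, function(a) metapath(mg, a))
  names(mps) <- df$abbreviation
  mps
}

.enumerateDf <- function(mg, maxLength) {
  stopifnot(is(mg, "Metagraph"), maxLength >= 0)
  st <- .stepTable(mg)
  me <- mg@metaedges
  res <- list()
  if (maxLength >= 1L && nrow(st) > 0L) {
    byFrom <- split(seq_len(nrow(st)), st$from)
    edges <- matrix(st$edge, ncol = 1L)
    invs <- matrix(st$inverted, ncol = 1L)
    endT <- st$to
    res[[1L]] <- list(edges = edges, invs = invs)
    len <- 1L
    while (len < maxLength) {
      ext <- byFrom[endT]
      reps <- lengths(ext)
      if (sum(reps) == 0L) break
      ridx <- rep.int(seq_len(nrow(edges)), reps)
      sidx <- unlist(ext, use.names = FALSE)
      edges <- cbind(edges[ridx, , drop = FALSE], st$edge[sidx])
      invs <- cbind(invs[ridx, , drop = FALSE], st$inverted[sidx])
      endT <- st$to[sidx]
      len <- len + 1L
      res[[len]] <- list(edges = edges, invs = invs)
    }
  }
  out <- lapply(res, function(r) .canonicalizeEnum(mg, r$edges, r$invs))
  out <- out[!vapply(out, is.null, logical(1))]
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(abbreviation = character(), length = integer(),
                     source = character(), target = character(),
                     stringsAsFactors = FALSE)
    df$types <- list()
  }
  rownames(df) <- NULL
  df
}

# keep canonical orientation rows; returns summary data.frame
.canonicalizeEnum <- function(mg, edges, invs) {
  me <- mg@metaedges
  n <- nrow(edges)
  if (n == 0L) return(NULL)
  L <- ncol(edges)
  srcT <- ifelse(invs[, 1L], me$target[edges[, 1L]], me$source[edges[, 1L]])
  abbrev <- srcT
  endT <- srcT
  typesM <- matrix("", nrow = n, ncol = L + 1L)
  typesM[, 1L] <- srcT
  for (k in seq_len(L)) {
    tok <- .stepToken(me, edges[, k], invs[, k])
    endT <- ifelse(invs[, k], me$source[edges[, k]], me$target[edges[, k]])
    typesM[, k + 1L] <- endT
    abbrev <- paste0(abbrev, tok, endT)
  }
  # reverse abbreviation
  rabbrev <- endT
  for (k in rev(seq_len(L))) {
    rtok <- .stepToken(me, edges[, k], !invs[, k])
    prevT <- ifelse(invs[, k], me$target[edges[, k]], me$source[edges[, k]])
    rabbrev <- paste0(rabbrev, rtok, prevT)
  }
  keep <- vapply(seq_len(n), function(i) .clexLe(abbrev[i], rabbrev[i]), logical(1))
  df <- data.frame(abbreviation = abbrev[keep], length = L,
                   source = srcT[keep], target = endT[keep],
                   stringsAsFactors = FALSE)
  df$types <- lapply(which(keep), function(i) typesM[i, ])
  df
}

.hetpathEnv <- new.env(parent = emptyenv())

# cheap schema signature for memoisation
.mgSignature <- function(mg) {
  paste(c(mg@metanodes$abbreviation,
          metaedgeAbbrev(mg@metaedges),
          mg@metaedges$directed), collapse = "|")
}

# number of metapaths of a given length between two metanodes (unordered),
# under the reverse-deduplicated enumeration convention
.metapathCountBetween <- function(mg, srcMn, tgtMn, len) {
  key <- paste0("mpcount:", .mgSignature(mg), ":", len)
  df <- .hetpathEnv[[key]]
  if (is.null(df)) {
    df <- .enumerateDf(mg, len)
    .hetpathEnv[[key]] <- df
  }
  sum(df$length == len &
        ((df$source == srcMn & df$target == tgtMn) |
           (df$source == tgtMn & df$target == srcMn)))
}
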