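# Deterministic synthetic hetnets for testing and simulation, plus the
# small named toy networks used throughout the documentation.

#' Generate a synthetic hetnet
#'
#' Builds a deterministic random hetnet from a specification: a metagraph,
#' per-metanode node counts, and per-metaedge either an edge density, an
#' exact edge count, explicit edges, or exact degree sequences.  Edges are
#' drawn as a uniform sample without replacement from the allowed pair set
#' (no self-loops, no duplicates); degree sequences are realized greedily
#' (Gale-Ryser / Havel-Hakimi style) and then shuffled by XSwap so the
#' realization is uniform-ish while the degrees stay exact.  Generation is
#' a pure function of the spec (including its seed).
#'
#' @param spec a list with elements:
#'   \describe{
#'     \item{metanodes}{data.frame with \code{identifier},
#'       \code{abbreviation}, \code{count}.}
#'     \item{metaedges}{list of lists with \code{source}, \code{target},
#'       \code{kind}, \code{abbreviation}, optional \code{directed}
#'       (default \code{FALSE}), and exactly one of \code{density},
#'       \code{nEdges}, \code{edges} (2-column index matrix) or
#'       \code{degrees} (list with \code{source} and \code{target} vectors;
#'       one vector for same-metanode metaedges).}
#'     \item{seed}{integer seed (default 0).}
#'   }
#' @return a \linkS4class{Hetnet}.
#' @examples
#' spec <- list(
#'   metanodes = data.frame(identifier = c("Compound", "Gene"),
#'                          abbreviation = c("C", "G"), count = c(4, 6)),
#'   metaedges = list(list(source = "C", target = "G", kind = "binds",
#'                         abbreviation = "b", density = 0.3)),
#'   seed = 1)
#' makeFixture(spec)
#' @export
makeFixture <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$metanodes), !is.null(spec$metaedges))
  seed <- spec$seed %||% 0L
  mn <- as.data.frame(spec$metanodes, stringsAsFactors = FALSE)
  stopifnot(all(c("identifier", "abbreviation", "count") %in% names(mn)))
  meList <- spec$metaedges
  meDf <- do.call(rbind, lapply(meList, function(e) {
    data.frame(source = e$source, target = e$target, kind = e$kind,
               abbreviation = e$abbreviation,
               directed = isTRUE(e$directed), stringsAsFactors = FALSE)
  }))
  mg <- metagraph(mn[c("identifier", "abbreviation")], meDf)
  counts <- setNames(mn$count, mn$abbreviation)
  nodes <- lapply(setNames(names(counts), names(counts)), function(ab) {
    sprintf("%s%03d", tolower(ab), seq_len(counts[[ab]]))
  })
  full <- metaedgeAbbrev(mg@metaedges)
  # metaedges may have been reordered by metagraph(); map back by abbrev
  specAb <- metaedgeAbbrev(meDf)
  adj <- list()
  for (k in seq_along(full)) {
    ab <- full[k]
    e <- meList[[match(ab, specAb)]]
    row <- mg@metaedges[k, ]
    nS <- counts[[row$source]]; nT <- counts[[row$target]]
    sameMn <- row$source == row$target
    adj[[ab]] <- .fixtureAdj(e, row, nS, nT, .deriveSeed(seed, ab))
  }
  hetnet(mg, nodes, adj)
}

# allowed (i, j) pair index set sizes and decode helpers
.fixtureAdj <- function(e, row, nS, nT, seed) {
  sameMn <- row$source == row$target
  build <- function(i, j) {
    if (sameMn && any(i == j)) {
      .stopf("hetpath_validation_error", "self-loop in fixture spec for %s", row$abbreviation)
    }
    if (sameMn && !row$directed) {
      ii <- pmin(i, j); jj <- pmax(i, j)
      if (anyDuplicated(cbind(ii, jj))) {
        .stopf("hetpath_validation_error", "duplicate edge in fixture spec")
      }
      i <- c(ii, jj); j <- c(jj, ii)
    } else if (anyDuplicated(cbind(i, j))) {
      .stopf("hetpath_validation_error", "duplicate edge in fixture spec")
    }
    Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nS, nT))
  }
  if (!is.null(e$edges)) {
    el <- as.matrix(e$edges)
    return(build(as.integer(el[, 1L]), as.integer(el[, 2L])))
  }
  if (!is.null(e$degrees)) {
    el <- .degreeSequenceEdges(e$degrees, nS, nT, sameMn, row$directed, seed)
    return(build(el[, 1L], el[, 2L]))
  }
  nPairs <- if (!sameMn) nS * nT else if (row$directed) nS * (nS - 1L) else nS * (nS - 1L) / 2L
  nEdges <- if (!is.null(e$nEdges)) e$nEdges else {
    if (is.null(e$density) || e$density < 0 || e$density > 1) {
      .stopf("hetpath_validation_error", "metaedge %s needs density in [0,1], nEdges, edges or degrees",
             row$abbreviation)
    }
    round(e$density * nPairs)
  }
  if (nEdges > nPairs) .stopf("hetpath_validation_error", "too many edges requested")
  pick <- .withSeed(seed, sort(sample.int(nPairs, nEdges)))
  if (!sameMn) {
    i <- ((pick - 1L) %% nS) + 1L
    j <- ((pick - 1L) %/% nS) + 1L
  } else if (row$directed) {
    # enumerate ordered pairs skipping the diagonal
    i <- ((pick - 1L) %% nS) + 1L
    j <- ((pick - 1L) %/% nS) + 1L
    j <- ifelse(j >= i, j + 1L, j)
  } else {
    # enumerate i < j pairs
    idx <- pick - 1L
    j <- floor((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - j * (j - 1) / 2
    i <- as.integer(i + 1L); j <- as.integer(j + 1L)
  }
  build(i, j)
}

# realize exact degree sequences: greedy construction, then XSwap shuffle
.degreeSequenceEdges <- function(degrees, nS, nT, sameMn, directed, seed) {
  if (sameMn && !directed) {
    d <- as.integer(degrees$source %||% degrees)
    stopifnot(length(d) == nS)
    if (sum(d) %% 2L != 0L) .stopf("hetpath_validation_error", "degree sequence has odd sum")
    # Havel-Hakimi
    res <- d
    edges <- matrix(integer(), ncol = 2L)
    repeat {
      v <- which.max(res)
      if (res[v] == 0L) break
      k <- res[v]
      res[v] <- 0L
      others <- order(-res)
      others <- others[others != v & res[others] > 0L][seq_len(min(k, nS))]
      if (length(others) < k) .stopf("hetpath_validation_error", "degree sequence is not graphical")
      res[others] <- res[others] - 1L
      edges <- rbind(edges, cbind(pmin(v, others), pmax(v, others)))
    }
  } else {
    ds <- as.integer(degrees$source)
    dt <- as.integer(degrees$target)
    stopifnot(length(ds) == nS, length(dt) == nT)
    if (sum(ds) != sum(dt)) .stopf("hetpath_validation_error", "degree sequences must have equal sums")
    res <- ds
    rt <- dt
    edges <- matrix(integer(), ncol = 2L)
    for (v in order(-res)) {
      k <- res[v]
      if (k == 0L) next
      tOrd <- order(-rt)
      tOrd <- tOrd[rt[tOrd] > 0L]
      if (sameMn) tOrd <- tOrd[tOrd != v]
      if (length(tOrd) < k) .stopf("hetpath_validation_error", "degree sequence is not graphical")
      sel <- tOrd[seq_len(k)]
      rt[sel] <- rt[sel] - 1L
      edges <- rbind(edges, cbind(v, sel))
    }
  }
  if (nrow(edges) >= 2L) {
    res <- xswapEdges(edges, multiplier = 10, seed = seed,
                      undirected = sameMn && !directed)
    edges <- res$edges
  }
  edges
}

#' Toy hetnets used in examples and tests
#'
#' \code{toyT1}: one metanode G with metaedge GiG forming the triangle
#' g1-g2-g3.  \code{toyT2}: metanodes C, G with metaedge CbG and edges
#' c1-g1, c1-g2, c2-g2 (g3 isolated).  \code{toyT2prime}: metanodes C, D
#' with metaedge CtD and edges c1-d1, c1-d2, c2-d1.
#'
#' @return a \linkS4class{Hetnet}.
#' @export
toyT1 <- function() {
  mg <- metagraph(data.frame(identifier = "Gene", abbreviation = "G"),
                  data.frame(source = "G", target = "G", kind = "interacts",
                             abbreviation = "i", directed = FALSE))
  a <- Matrix::sparseMatrix(i = c(1, 2, 1, 3, 2, 3), j = c(2, 1, 3, 1, 3, 2),
                            x = 1, dims = c(3, 3))
  hetnet(mg, list(G = c("g1", "g2", "g3")), list(GiG = a))
}

#' @rdname toyT1
#' @export
toyT2 <- function() {
  mg <- metagraph(data.frame(identifier = c("Compound", "Gene"),
                             abbreviation = c("C", "G")),
                  data.frame(source = "C", target = "G", kind = "binds",
                             abbreviation = "b", directed = FALSE))
  a <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2), x = 1, dims = c(2, 3))
  hetnet(mg, list(C = c("c1", "c2"), G = c("g1", "g2", "g3")), list(CbG = a))
}

#' @rdname toyT1
#' @export
toyT2prime <- function() {
  mg <- metagraph(data.frame(identifier = c("Compound", "Disease"),
                             abbreviation = c("C", "D")),
                  data.frame(source = "C", target = "D", kind = "treats",
                             abbreviation = "t", directed = FALSE))
  a <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 1), x = 1, dims = c(2, 2))
  hetnet(mg, list(C = c("c1", "c2"), D = c("d1", "d2")), list(CtD = a))
}

#' The Hetionet v1.0 metagraph schema
#'
#' The 11-metanode, 24-metaedge schema of Hetionet v1.0 (the integrative
#' biomedical knowledge graph), bundled with the package.  The
#' gene-regulates-gene metaedge is the only directed one.  Node counts per
#' metanode are available via \code{hetionetNodeCounts}.
#'
#' @return a \linkS4class{Metagraph}.
#' @export
hetionetMetagraph <- function() {
  path <- system.file("extdata", "hetionet-v1.0-metagraph.json", package = "hetpath")
  if (!nzchar(path) || !file.exists(path)) {
    .stopf("hetpath_load_error",
           "bundled Hetionet metagraph not found; reinstall the package or supply extdata/hetionet-v1.0-metagraph.json")
  }
  readMetagraph(path)
}

#' @rdname hetionetMetagraph
#' @return \code{hetionetNodeCounts} returns a named integer vector of node
#'   counts per metanode abbreviation.
#' @export
hetionetNodeCounts <- function() {
  c(A = 402L, BP = 11381L, CC = 1391L, C = 1552L, D = 137L, G = 20945L,
    MF = 2884L, PW = 1822L, PC = 345L, SE = 5734L, S = 438L)
}
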