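#' Hetnet: a typed network stored as one biadjacency matrix per metaedge
#'
#' A \code{Hetnet} couples a \linkS4class{Metagraph} with one node table per
#' metanode and one boolean (bi)adjacency matrix per metaedge (rows = source
#' metanode nodes, columns = target metanode nodes).  Node order within a
#' metanode is fixed at creation, sorted by identifier, so matrix indices
#' are reproducible.  On disk a hetnet is a directory:
#' \preformatted{
#'   metagraph.json
#'   nodes/<Metanode>.tsv        (columns: position, identifier, name)
#'   edges/<metaedge>.mtx        (MatrixMarket sparse, density < threshold)
#'   edges/<metaedge>.tsv        (dense 0/1 table otherwise)
#' }
#' Matrices are loaded lazily: only requested metaedges are read into
#' memory.  Undirected metaedges between the same metanode are stored as
#' symmetric matrices with a zero diagonal (no self-loops, no duplicate
#' edges).
#'
#' @slot metagraph the \linkS4class{Metagraph}.
#' @slot nodes named list (by metanode abbreviation) of data.frames with
#'   columns \code{identifier}, \code{name}.
#' @slot adjEnv environment caching loaded adjacency matrices by full
#'   metaedge abbreviation.
#' @slot dir directory backing the store (\code{""} for in-memory stores).
#' @slot cache environment used by the DWPC segment cache.
#' @exportClass Hetnet
setClass("Hetnet", slots = c(metagraph = "Metagraph", nodes = "list",
                             adjEnv = "environment", dir = "character",
                             cache = "environment"))

#' A permuted hetnet with provenance
#'
#' @slot baseFingerprint fingerprint of the store that was permuted.
#' @slot seed integer seed used to derive per-metaedge swap streams.
#' @slot multiplier swap attempts per edge.
#' @slot swapStats data.frame with per-metaedge \code{attempted} and
#'   \code{accepted} swap counts.
#' @exportClass PermutedHetnet
setClass("PermutedHetnet", contains = "Hetnet",
         slots = c(baseFingerprint = "character", seed = "integer",
                   multiplier = "numeric", swapStats = "data.frame"))

setValidity("Hetnet", function(object) {
  mg <- object@metagraph
  msgs <- character()
  mnAb <- mg@metanodes$abbreviation
  if (!setequal(names(object@nodes), mnAb)) {
    return("node tables must be named by metanode abbreviation, one per metanode")
  }
  for (ab in mnAb) {
    tab <- object@nodes[[ab]]
    if (!all(c("identifier", "name") %in% names(tab))) {
      msgs <- c(msgs, sprintf("node table %s needs identifier and name columns", ab))
      next
    }
    if (is.unsorted(tab$identifier, strictly = TRUE)) {
      msgs <- c(msgs, sprintf("node table %s must be strictly sorted by identifier", ab))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "Hetnet", function(object) {
  mg <- object@metagraph
  nNodes <- sum(vapply(object@nodes, nrow, integer(1)))
  cat(sprintf("%s with %d nodes of %d types, %d metaedges%s\n",
              class(object), nNodes, nrow(mg@metanodes), nrow(mg@metaedges),
              if (nzchar(object@dir)) paste0(" <", object@dir, ">") else ""))
})

# normalize a node spec (char vector of ids or data.frame) to a sorted table
.nodeTable <- function(x, mnAbbrev) {
  if (is.character(x)) x <- data.frame(identifier = x, name = x, stringsAsFactors = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$name)) x$name <- x$identifier
  if (anyDuplicated(x$identifier)) {
    .stopf("hetpath_load_error", "duplicate node identifiers for metanode %s", mnAbbrev)
  }
  x <- x[order(x$identifier, method = "radix"), c("identifier", "name"), drop = FALSE]
  rownames(x) <- NULL
  x
}

# validate and coerce one adjacency matrix to a sparse 0/1 dgCMatrix
.coerceAdj <- function(m, meRow, nSrc, nTgt, abbrev) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(m) != nSrc || ncol(m) != nTgt) {
    .stopf("hetpath_load_error",
           "adjacency matrix for metaedge %s has shape %dx%d, expected %dx%d",
           abbrev, nrow(m), ncol(m), nSrc, nTgt)
  }
  if (length(m@x) && !all(m@x %in% c(0, 1))) {
    .stopf("hetpath_load_error", "adjacency entries for metaedge %s must be 0/1", abbrev)
  }
  m <- Matrix::drop0(m)
  if (meRow$source == meRow$target) {
    if (any(Matrix::diag(m) != 0)) {
      .stopf("hetpath_load_error", "self-loops are not allowed (metaedge %s)", abbrev)
    }
    if (!meRow$directed && !Matrix::isSymmetric(m)) {
      .stopf("hetpath_load_error",
             "undirected same-metanode metaedge %s must have a symmetric matrix", abbrev)
    }
  }
  m
}

#' Construct an in-memory hetnet
#'
#' @param mg a \linkS4class{Metagraph}.
#' @param nodes named list (by metanode abbreviation) of node identifier
#'   vectors or data.frames with columns \code{identifier}, \code{name}.
#' @param adjacency named list (by full metaedge abbreviation, e.g.
#'   \code{"CbG"}) of 0/1 matrices; missing metaedges default to all-zero.
#' @return a \linkS4class{Hetnet}.
#' @export
hetnet <- function(mg, nodes, adjacency = list()) {
  stopifnot(is(mg, "Metagraph"))
  mnAb <- mg@metanodes$abbreviation
  nodes <- lapply(setNames(mnAb, mnAb), function(ab) {
    if (is.null(nodes[[ab]])) .stopf("hetpath_load_error", "missing node table for metanode %s", ab)
    .nodeTable(nodes[[ab]], ab)
  })
  me <- mg@metaedges
  full <- if (nrow(me)) metaedgeAbbrev(me) else character()
  unknown <- setdiff(names(adjacency), full)
  if (length(unknown)) {
    .stopf("hetpath_key_error", "adjacency given for unknown metaedge: %s",
           paste(unknown, collapse = ", "))
  }
  env <- new.env(parent = emptyenv())
  for (k in seq_along(full)) {
    ab <- full[k]
    nSrc <- nrow(nodes[[me$source[k]]])
    nTgt <- nrow(nodes[[me$target[k]]])
    m <- adjacency[[ab]]
    if (is.null(m)) {
      m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nSrc, nTgt))
    }
    env[[ab]] <- .coerceAdj(m, me[k, ], nSrc, nTgt, ab)
  }
  new("Hetnet", metagraph = mg, nodes = nodes, adjEnv = env, dir = "",
      cache = new.env(parent = emptyenv()))
}

#' @rdname hetnet
#' @param store a \linkS4class{Hetnet}.
#' @param metanode a metanode abbreviation.
#' @return \code{nodeTable} returns the node data.frame; \code{nodeIds} the
#'   sorted identifier vector.
#' @export
nodeTable <- function(store, metanode) {
  tab <- store@nodes[[metanode]]
  if (is.null(tab)) .stopf("hetpath_key_error", "unknown metanode: %s", metanode)
  tab
}

#' @rdname hetnet
#' @export
nodeIds <- function(store, metanode) nodeTable(store, metanode)$identifier

# resolve a metaedge argument (full abbreviation or row index) to row index
.meRow <- function(store, metaedge) {
  if (is.numeric(metaedge)) return(as.integer(metaedge))
  .meIndex(store@metagraph, metaedge)
}

#' Adjacency matrix of one metaedge
#'
#' @param store a \linkS4class{Hetnet}.
#' @param metaedge full metaedge abbreviation (e.g. \code{"CbG"}) or row
#'   index into \code{metaedges(metagraph)}.
#' @param inverted if \code{TRUE}, return the transpose (target-to-source
#'   traversal).
#' @return a sparse \code{dgCMatrix} with 0/1 entries.
#' @export
adjacencyMatrix <- function(store, metaedge, inverted = FALSE) {
  k <- .meRow(store, metaedge)
  me <- store@metagraph@metaedges
  ab <- metaedgeAbbrev(me)[k]
  m <- store@adjEnv[[ab]]
  if (is.null(m)) {
    if (!nzchar(store@dir)) {
      .stopf("hetpath_load_error", "no adjacency matrix for metaedge %s", ab)
    }
    m <- .readAdjFile(store, k, ab)
    store@adjEnv[[ab]] <- m
  }
  if (inverted) Matrix::t(m) else m
}

#' Per-metaedge node degrees
#'
#' Source degrees are row sums and target degrees are column sums of the
#' metaedge's biadjacency matrix.  For directed same-metanode metaedges the
#' source side counts out-edges and the target side in-edges.
#'
#' @inheritParams adjacencyMatrix
#' @return list with numeric vectors \code{source} and \code{target}.
#' @export
metaedgeDegrees <- function(store, metaedge, inverted = FALSE) {
  m <- adjacencyMatrix(store, metaedge, inverted = inverted)
  list(source = Matrix::rowSums(m), target = Matrix::colSums(m))
}

#' Degree-weighted adjacency matrix
#'
#' Entry (i, j) is \eqn{A_{ij} (d_i d_j)^{-w}} where the degrees are
#' metaedge-specific; entries with \eqn{A_{ij} = 0} are 0, so zero degrees
#' never enter.  \code{w = 0} reproduces the boolean adjacency.
#'
#' @inheritParams adjacencyMatrix
#' @param w damping exponent, a non-negative real.
#' @return a sparse \code{dgCMatrix}.
#' @export
dampedAdjacency <- function(store, metaedge, w = 0.5, inverted = FALSE) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0) {
    .stopf("hetpath_validation_error", "damping exponent w must be a single number >= 0")
  }
  m <- adjacencyMatrix(store, metaedge, inverted = inverted)
  ds <- Matrix::rowSums(m)
  dt <- Matrix::colSums(m)
  sw <- ifelse(ds > 0, ds^(-w), 0)
  tw <- ifelse(dt > 0, dt^(-w), 0)
  Matrix::Diagonal(x = sw) %*% m %*% Matrix::Diagonal(x = tw)
}

#' Stable fingerprint of a hetnet's node tables and edges
#'
#' A cheap (non-cryptographic) hash used to tie permuted stores and cached
#' DWPC segments to the store they came from.
#'
#' @param store a \linkS4class{Hetnet}.
#' @return a character scalar.
#' @export
hetnetFingerprint <- function(store) {
  me <- store@metagraph@metaedges
  full <- if (nrow(me)) metaedgeAbbrev(me) else character()
  h <- 17
  mix <- function(h, v) {
    for (x in v) h <- (h * 31 + x) %% 2147483647
    h
  }
  for (ab in store@metagraph@metanodes$abbreviation) {
    h <- mix(h, nrow(store@nodes[[ab]]))
    h <- mix(h, sum(utf8ToInt(paste(store@nodes[[ab]]$identifier, collapse = "")) %% 97))
  }
  for (k in seq_along(full)) {
    m <- adjacencyMatrix(store, k)
    idx <- Matrix::which(m != 0)
    h <- mix(h, c(length(idx), sum(idx %% 2147483647) %% 2147483647))
  }
  sprintf("%x", as.integer(h))
}

#' Edge list of one metaedge
#'
#' @inheritParams adjacencyMatrix
#' @param ids return node identifiers instead of integer positions.
#' @return a two-column matrix (source, target); for undirected
#'   same-metanode metaedges, one row per unordered pair (upper triangle).
#' @export
edgeList <- function(store, metaedge, ids = FALSE) {
  k <- .meRow(store, metaedge)
  me <- store@metagraph@metaedges
  m <- adjacencyMatrix(store, k)
  idx <- Matrix::which(m != 0, arr.ind = TRUE)
  if (me$source[k] == me$target[k] && !me$directed[k]) {
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  }
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("source", "target"))
  if (ids) {
    cbind(source = nodeIds(store, me$source[k])[idx[, 1L]],
          target = nodeIds(store, me$target[k])[idx[, 2L]])
  } else {
    idx
  }
}

## ------------------------------------------------------------------ disk IO

.compressExts <- c(gz = "gz", bz2 = "bz2", xz = "xz", zip = "zip")

# find edges/<ab>.<fmt>[.<comp>]; returns list(path, fmt, comp) or NULL
.findEdgeFile <- function(dir, ab) {
  for (fmt in c("mtx", "tsv")) {
    for (comp in c("", ".gz", ".bz2", ".xz", ".zip")) {
      p <- file.path(dir, "edges", paste0(ab, ".", fmt, comp))
      if (file.exists(p)) return(list(path = p, fmt = fmt, comp = sub("^\\.", "", comp)))
    }
  }
  NULL
}

# a readable connection/path; compressed files are staged to a temp file
.stageReadable <- function(path, comp) {
  if (comp == "") return(path)
  tmp <- tempfile()
  if (comp == "zip") {
    files <- utils::unzip(path, list = TRUE)$Name
    utils::unzip(path, files = files[1L], exdir = dirname(tmp), overwrite = TRUE)
    return(file.path(dirname(tmp), files[1L]))
  }
  con <- switch(comp, gz = gzfile(path, "rb"), bz2 = bzfile(path, "rb"),
                xz = xzfile(path, "rb"))
  on.exit(close(con))
  writeBin(readBin(con, "raw", n = file.size(path) * 50 + 1e6), tmp)
  tmp
}

.readAdjFile <- function(store, k, ab) {
  me <- store@metagraph@metaedges
  hit <- .findEdgeFile(store@dir, ab)
  if (is.null(hit)) {
    .stopf("hetpath_load_error", "missing edge file for metaedge %s in %s",
           ab, store@dir)
  }
  path <- .stageReadable(hit$path, hit$comp)
  m <- if (hit$fmt == "mtx") {
    methods::as(Matrix::readMM(path), "CsparseMatrix")
  } else {
    as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  }
  nSrc <- nrow(store@nodes[[me$source[k]]])
  nTgt <- nrow(store@nodes[[me$target[k]]])
  .coerceAdj(m, me[k, ], nSrc, nTgt, ab)
}

#' Save a hetnet to a directory
#'
#' Matrices with density below \code{densityThreshold} are serialized as
#' MatrixMarket sparse files (\code{.mtx}); denser matrices as dense TSV.
#' Existing generated-data subdirectories (e.g. \code{path-counts/},
#' \code{permutations/}) are left untouched.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param dir output directory (created if needed).
#' @param densityThreshold density at or above which the dense format is
#'   used (the sparse rule is strictly "density < threshold").
#' @return the directory path, invisibly.
#' @export
saveHetnet <- function(store, dir, densityThreshold = 0.7) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2L) != 0L) {
    .stopf("hetpath_io_error", "cannot write to directory %s", dir)
  }
  writeMetagraph(store@metagraph, file.path(dir, "metagraph.json"))
  dir.create(file.path(dir, "nodes"), showWarnings = FALSE)
  dir.create(file.path(dir, "edges"), showWarnings = FALSE)
  mg <- store@metagraph
  for (k in seq_len(nrow(mg@metanodes))) {
    ab <- mg@metanodes$abbreviation[k]
    tab <- store@nodes[[ab]]
    out <- data.frame(position = seq_len(nrow(tab)) - 1L,
                      identifier = tab$identifier, name = tab$name)
    utils::write.table(out, file.path(dir, "nodes", paste0(mg@metanodes$identifier[k], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  me <- mg@metaedges
  full <- if (nrow(me)) metaedgeAbbrev(me) else character()
  for (k in seq_along(full)) {
    ab <- full[k]
    m <- adjacencyMatrix(store, k)
    density <- length(m@x) / prod(dim(m))
    base <- file.path(dir, "edges", ab)
    # remove stale serializations of this metaedge in either format
    old <- .findEdgeFile(dir, ab)
    while (!is.null(old)) {
      unlink(old$path)
      old <- .findEdgeFile(dir, ab)
    }
    if (density < densityThreshold) {
      Matrix::writeMM(m, paste0(base, ".mtx"))
    } else {
      utils::write.table(as.matrix(m), paste0(base, ".tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Load a hetnet from a directory
#'
#' Node tables and the metagraph are read eagerly; adjacency matrices are
#' read lazily on first access.
#'
#' @param dir a directory written by \code{\link{saveHetnet}}.
#' @param lazy if \code{FALSE}, load all adjacency matrices immediately.
#' @return a \linkS4class{Hetnet}.
#' @export
loadHetnet <- function(dir, lazy = TRUE) {
  if (!dir.exists(dir)) .stopf("hetpath_load_error", "no such directory: %s", dir)
  mg <- readMetagraph(file.path(dir, "metagraph.json"))
  nodesDir <- file.path(dir, "nodes")
  nodes <- list()
  for (k in seq_len(nrow(mg@metanodes))) {
    ab <- mg@metanodes$abbreviation[k]
    id <- mg@metanodes$identifier[k]
    path <- NULL
    for (comp in c("", ".gz", ".bz2", ".xz")) {
      p <- file.path(nodesDir, paste0(id, ".tsv", comp))
      if (file.exists(p)) { path <- p; break }
    }
    if (is.null(path)) {
      .stopf("hetpath_load_error", "missing node table for metanode %s (%s)", id, ab)
    }
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(identifier = "character", name = "character"))
    nodes[[ab]] <- .nodeTable(tab[c("identifier", "name")], ab)
  }
  store <- new("Hetnet", metagraph = mg, nodes = nodes,
               adjEnv = new.env(parent = emptyenv()), dir = dir,
               cache = new.env(parent = emptyenv()))
  if (!lazy) {
    me <- mg@metaedges
    for (ab in if (nrow(me)) metaedgeAbbrev(me) else character()) {
      adjacencyMatrix(store, ab)
    }
  }
  store
}

#' Build a hetnet from an edge-list table
#'
#' @param edges data.frame with columns \code{source_id},
#'   \code{metaedge} (full abbreviation) and \code{target_id}.
#' @param mg a \linkS4class{Metagraph}.
#' @param nodes optional named list of node identifier vectors per metanode
#'   (to include isolated nodes); identifiers present in \code{edges} are
#'   always included.
#' @return a \linkS4class{Hetnet}.
#' @export
hetnetFromEdgeList <- function(edges, mg, nodes = NULL) {
  stopifnot(all(c("source_id", "metaedge", "target_id") %in% names(edges)))
  me <- mg@metaedges
  full <- metaedgeAbbrev(me)
  bad <- setdiff(unique(edges$metaedge), full)
  if (length(bad)) {
    .stopf("hetpath_key_error", "unknown metaedge abbreviation in edge list: %s",
           paste(bad, collapse = ", "))
  }
  idSets <- lapply(setNames(mg@metanodes$abbreviation, mg@metanodes$abbreviation),
                   function(ab) as.character(nodes[[ab]] %||% character()))
  for (k in seq_along(full)) {
    sel <- edges$metaedge == full[k]
    idSets[[me$source[k]]] <- union(idSets[[me$source[k]]], edges$source_id[sel])
    idSets[[me$target[k]]] <- union(idSets[[me$target[k]]], edges$target_id[sel])
  }
  adj <- list()
  for (k in seq_along(full)) {
    sel <- which(edges$metaedge == full[k])
    srcIds <- sort(idSets[[me$source[k]]], method = "radix")
    tgtIds <- sort(idSets[[me$target[k]]], method = "radix")
    i <- match(edges$source_id[sel], srcIds)
    j <- match(edges$target_id[sel], tgtIds)
    if (me$source[k] == me$target[k]) {
      if (any(i == j)) .stopf("hetpath_load_error", "self-loop in metaedge %s", full[k])
      if (!me$directed[k]) {
        ii <- pmin(i, j); jj <- pmax(i, j)
        if (anyDuplicated(cbind(ii, jj))) {
          .stopf("hetpath_load_error", "duplicate edge in metaedge %s", full[k])
        }
        i <- c(ii, jj); j <- c(jj, ii)
      }
    }
    if (anyDuplicated(cbind(i, j))) {
      .stopf("hetpath_load_error", "duplicate edge in metaedge %s", full[k])
    }
    adj[[full[k]]] <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                           dims = c(length(srcIds), length(tgtIds)))
  }
  hetnet(mg, idSets, adj)
}

#' Compare two hetnets for equality
#'
#' Bit-exact comparison of metagraph tables, node tables and all adjacency
#' matrices.
#'
#' @param a,b \linkS4class{Hetnet} objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
hetnetIdentical <- function(a, b) {
  if (!identical(a@metagraph@metanodes, b@metagraph@metanodes)) return(FALSE)
  if (!identical(a@metagraph@metaedges, b@metagraph@metaedges)) return(FALSE)
  if (!identical(a@nodes, b@nodes)) return(FALSE)
  me <- a@metagraph@metaedges
  for (ab in if (nrow(me)) metaedgeAbbrev(me) else character()) {
    ma <- adjacencyMatrix(a, ab)
    mb <- adjacencyMatrix(b, ab)
    if (!identical(dim(ma), dim(mb))) return(FALSE)
    if (!isTRUE(all(ma == mb))) return(FALSE)
  }
  TRUE
}
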