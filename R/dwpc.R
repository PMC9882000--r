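#' DWPC result container
#'
#' The degree-weighted path count (DWPC) between a source and target node
#' along a metapath is the sum, over all simple paths conforming to the
#' metapath, of each path's path degree product \eqn{\prod (d_i d_j)^{-w}}.
#' With damping exponent \code{w = 0} the DWPC is the plain simple-path
#' count.  A \code{DwpcResult} holds the full source-by-target matrix for
#' one metapath.
#'
#' @slot metapath the \linkS4class{Metapath}.
#' @slot w damping exponent.
#' @slot matrix dense numeric matrix, rows = source metanode nodes,
#'   columns = target metanode nodes, dimnames = node identifiers.
#' @slot kind \code{"path-count"} (\code{w = 0}) or \code{"dwpc"}.
#' @slot method \code{"matrix"}, \code{"enumeration"} or \code{"approximate"}.
#' @slot approximate \code{TRUE} when complex segments were only
#'   approximately corrected.
#' @exportClass DwpcResult
setClass("DwpcResult", slots = c(metapath = "Metapath", w = "numeric",
                                 matrix = "matrix", kind = "character",
                                 method = "character", approximate = "logical"))

setValidity("DwpcResult", function(object) {
  if (any(object@matrix < -1e-12)) return("DWPC entries must be non-negative")
  TRUE
})

#' @export
setGeneric("dwpcMatrix", function(x) standardGeneric("dwpcMatrix"))

#' @describeIn DwpcResult-class The numeric matrix of path counts or DWPCs.
#' @param x a \code{DwpcResult}.
#' @export
setMethod("dwpcMatrix", "DwpcResult", function(x) x@matrix)

setMethod("show", "DwpcResult", function(object) {
  cat(sprintf("%s matrix for %s (w = %g, %dx%d, %s method%s)\n",
              object@kind, abbreviation(object@metapath), object@w,
              nrow(object@matrix), ncol(object@matrix), object@method,
              if (object@approximate) ", approximate" else ""))
})

## ----------------------------------------------------- correction routines

.zeroDiag <- function(m) {
  n <- min(dim(m))
  m[cbind(seq_len(n), seq_len(n))] <- 0
  m
}

#' DWPC correction formulas for repeated metanodes
#'
#' Building-block corrections used by the segmented matrix method.
#' \code{dwpcShortRepeat} handles a metanode repeated at both ends of two
#' consecutive segments (\code{XaXbX}): the product of the segment DWPC
#' matrices minus its diagonal, removing walks that return to the start
#' node.  \code{dwpcNested} handles \code{XaYbYcX}: the triple product
#' minus its diagonal (the inner \code{Y} repeat must already be corrected,
#' i.e. \code{Dyy} has a zero diagonal).  \code{dwpcOverlapping} handles
#' interleaved \code{XaYbXcY} by inclusion-exclusion over the two repeats
#' (\code{x1 = x3} and \code{y2 = y4}).
#'
#' @param D1,D2 square segment DWPC matrices over the same metanode with
#'   zero diagonals.
#' @return a numeric matrix with the stated correction applied.
#' @export
dwpcShortRepeat <- function(D1, D2) {
  if (!all(dim(D1) == dim(D2)) || nrow(D1) != ncol(D1)) {
    .stopf("hetpath_validation_error",
           "dwpcShortRepeat requires square matrices of equal shape")
  }
  .zeroDiag(D1 %*% D2)
}

#' @rdname dwpcShortRepeat
#' @param Dxy,Dyy,Dyx segment matrices for \code{X..Y}, \code{Y..Y}
#'   (zero diagonal) and \code{Y..X}.
#' @export
dwpcNested <- function(Dxy, Dyy, Dyx) {
  if (ncol(Dxy) != nrow(Dyy) || ncol(Dyy) != nrow(Dyx) || nrow(Dxy) != ncol(Dyx)) {
    .stopf("hetpath_validation_error", "dwpcNested matrices are not conformable")
  }
  .zeroDiag(Dxy %*% Dyy %*% Dyx)
}

#' @rdname dwpcShortRepeat
#' @param Dab,Dba,Dab2 segment matrices for \code{X..Y}, \code{Y..X} and
#'   \code{X..Y} (in metapath order).
#' @export
dwpcOverlapping <- function(Dab, Dba, Dab2) {
  if (ncol(Dab) != nrow(Dba) || ncol(Dba) != nrow(Dab2) ||
      nrow(Dab) != nrow(Dab2) || ncol(Dab) != ncol(Dab2)) {
    .stopf("hetpath_validation_error", "dwpcOverlapping matrices are not conformable")
  }
  d1 <- rowSums(Dab * t(Dba))            # diag(Dab %*% Dba)
  d2 <- rowSums(Dba * t(Dab2))           # diag(Dba %*% Dab2)
  Dab %*% Dba %*% Dab2 -
    d1 * Dab2 -
    Dab * matrix(d2, nrow(Dab), length(d2), byrow = TRUE) +
    Dab * t(Dba) * Dab2
}

## --------------------------------------------------------- matrix pipeline

# dense damped adjacency for one metapath step
.stepMatrix <- function(store, mp, k, w) {
  as.matrix(dampedAdjacency(store, mp@edges[k], w = w, inverted = mp@inverted[k]))
}

# plain product of steps a..b-1 (node positions a..b)
.chainProduct <- function(ctx, a, b) {
  m <- ctx$mats[[a]]
  k <- a + 1L
  while (k < b) {
    m <- m %*% ctx$mats[[k]]
    k <- k + 1L
  }
  m
}

.evalPlan <- function(ctx, node) {
  key <- if (ctx$useCache) paste0(.subAbbrev(ctx$mp, node$range[1L], node$range[2L]),
                                  "|w=", ctx$w, "|", ctx$approx) else NULL
  if (!is.null(key)) {
    hit <- .cacheGet(ctx$store, key)
    if (!is.null(hit)) return(hit)
  }
  a <- node$range[1L]; b <- node$range[2L]
  val <- switch(node$kind,
    chain = .chainProduct(ctx, a, b),
    product = Reduce(`%*%`, lapply(node$children, .evalPlan, ctx = ctx)),
    diag = .zeroDiag(Reduce(`%*%`, lapply(node$children, .evalPlan, ctx = ctx))),
    overlap = {
      ch <- lapply(node$children, .evalPlan, ctx = ctx)
      dwpcOverlapping(ch[[1L]], ch[[2L]], ch[[3L]])
    },
    complex = if (ctx$approx) .approxComplex(ctx, a, b) else .enumRange(ctx, a, b),
    .stopf("hetpath_validation_error", "unknown plan node kind: %s", node$kind)
  )
  if (!is.null(key)) .cachePut(ctx$store, key, val)
  val
}

# complex leaf, approximate: correct only the first repeated metanode's
# first pair of occurrences; all other repeats are left as walks
.approxComplex <- function(ctx, a, b) {
  types <- ctx$types[a:b]
  firstRep <- NULL
  seen <- character()
  for (k in seq_along(types)) {
    if (types[k] %in% seen) { firstRep <- types[k]; break }
    seen <- c(seen, types[k])
  }
  occ <- which(types == firstRep) + a - 1L
  p <- occ[1L]; q <- occ[2L]
  mid <- .zeroDiag(.chainProduct(ctx, p, q))
  out <- if (p > a) .chainProduct(ctx, a, p) %*% mid else mid
  if (q < b) out <- out %*% .chainProduct(ctx, q, b)
  out
}

# exact DWPC of the sub-metapath spanning node positions a..b, by DFS
.enumRange <- function(ctx, a, b) {
  sub <- new("Metapath", metagraph = ctx$mp@metagraph,
             edges = ctx$mp@edges[a:(b - 1L)],
             inverted = ctx$mp@inverted[a:(b - 1L)])
  .enumDwpc(ctx$store, sub, ctx$w, ctx$budget)
}

.enumDwpc <- function(store, mp, w, budget) {
  types <- .typeSeq(mp)
  uty <- unique(types)
  typeSizes <- vapply(uty, function(t) nrow(store@nodes[[t]]), integer(1))
  steps <- lapply(seq_len(length(mp)), function(k) {
    m <- dampedAdjacency(store, mp@edges[k], w = w, inverted = mp@inverted[k])
    tm <- methods::as(Matrix::t(m), "CsparseMatrix")   # CSR of m
    list(p = tm@p, j = tm@i, x = tm@x)
  })
  tryCatch(
    .cppEnumDwpc(steps, match(types, uty) - 1L, unname(typeSizes), budget),
    error = function(e) {
      if (grepl("budget exceeded", conditionMessage(e))) {
        .stopf("hetpath_budget_error", "%s", conditionMessage(e))
      }
      stop(e)
    }
  )
}

## ------------------------------------------------------------ segment cache

.cacheGet <- function(store, key) {
  entry <- store@cache[[key]]
  if (is.null(entry)) return(NULL)
  n <- (store@cache[[".tick"]] %||% 0) + 1
  store@cache[[".tick"]] <- n
  entry$stamp <- n
  store@cache[[key]] <- entry
  entry$value
}

.cachePut <- function(store, key, value) {
  cap <- getOption("hetpath.cacheSize", 256L)
  keys <- setdiff(ls(store@cache, all.names = FALSE), character())
  if (length(keys) >= cap) {
    stamps <- vapply(keys, function(k) store@cache[[k]]$stamp, numeric(1))
    rm(list = keys[which.min(stamps)], envir = store@cache)
  }
  n <- (store@cache[[".tick"]] %||% 0) + 1
  store@cache[[".tick"]] <- n
  store@cache[[key]] <- list(value = value, stamp = n)
  invisible(NULL)
}

## ------------------------------------------------------------- entry point

#' Compute the path-count / DWPC matrix of a metapath
#'
#' Counts only simple paths (no node visited twice).  The default
#' \code{"matrix"} method segments the metapath by its repeated-metanode
#' pattern and combines plain matrix products with diagonal-subtraction and
#' inclusion-exclusion corrections; segments that are too complex for the
#' closed-form corrections (4+ occurrences of a metanode, or interleavings
#' like ABCABC) fall back to exhaustive enumeration.  \code{"enumeration"}
#' forces the exhaustive depth-first traversal for the whole metapath (the
#' independent reference implementation).  \code{"approximate"} corrects
#' repeats in simple patterns exactly but only the first repeat inside
#' complex segments; its result is an upper bound on the exact DWPC.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param metapath a \linkS4class{Metapath} or its abbreviation.
#' @param w damping exponent (non-negative; \code{0} gives path counts).
#' @param method \code{"matrix"} (default), \code{"enumeration"} or
#'   \code{"approximate"}.
#' @param budget maximum number of path extensions allowed in enumeration;
#'   exceeding it raises a resource error.
#' @param cache reuse per-segment results cached on the store.  Caching is
#'   semantically invisible: results are identical with \code{cache = FALSE}.
#' @return a \linkS4class{DwpcResult}.
#' @examples
#' store <- toyT1()
#' dwpcMatrix(dwpc(store, "GiGiG", w = 0.5))
#' @export
dwpc <- function(store, metapath, w = 0.5,
                 method = c("matrix", "enumeration", "approximate"),
                 budget = 1e8, cache = TRUE) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("matrix", "enumeration", "approximate")) {
    .stopf("hetpath_validation_error", "unsupported dwpc method: %s", method)
  }
  method <- match.arg(method)
  if (is.character(metapath)) metapath <- .parseMetapath(store@metagraph, metapath)
  stopifnot(is(metapath, "Metapath"))
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0) {
    .stopf("hetpath_validation_error", "damping exponent w must be a single number >= 0")
  }
  types <- .typeSeq(metapath)
  approximateUsed <- FALSE
  if (method == "enumeration") {
    mat <- .enumDwpc(store, metapath, w, budget)
  } else {
    approx <- method == "approximate"
    ctx <- list(store = store, mp = metapath, w = w, types = types,
                budget = budget, useCache = isTRUE(cache), approx = approx,
                mats = lapply(seq_len(length(metapath)), function(k)
                  .stepMatrix(store, metapath, k, w)))
    plan <- .segmentPlan(types, 1L, length(types))
    mat <- .evalPlan(ctx, plan)
    approximateUsed <- approx && .planHasComplex(plan)
  }
  mat <- as.matrix(mat)
  mat[mat < 0 & mat > -1e-12] <- 0    # clip tiny negative round-off
  dimnames(mat) <- list(nodeIds(store, types[1L]), nodeIds(store, tail(types, 1L)))
  new("DwpcResult", metapath = metapath, w = w, matrix = mat,
      kind = if (w == 0) "path-count" else "dwpc",
      method = if (method == "matrix") "matrix" else method,
      approximate = approximateUsed)
}
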