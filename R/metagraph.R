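#' Metagraph: the type schema of a hetnet
#'
#' A metagraph records the node types (metanodes) and edge types (metaedges)
#' that a hetnet may contain.  Metanodes carry a unique abbreviation (e.g.
#' \code{"G"} for Gene, \code{"PW"} for Pathway); metaedges connect two
#' metanodes with a kind (e.g. \code{"interacts"}), a kind abbreviation
#' (e.g. \code{"i"}) and a directionality flag.  All metapath and DWPC
#' computation is keyed on this schema.
#'
#' @slot metanodes data.frame with columns \code{identifier}, \code{abbreviation}.
#' @slot metaedges data.frame with columns \code{source}, \code{target}
#'   (metanode abbreviations), \code{kind}, \code{abbreviation} (kind
#'   abbreviation), \code{directed} (logical).
#' @exportClass Metagraph
setClass("Metagraph", slots = c(metanodes = "data.frame", metaedges = "data.frame"))

setValidity("Metagraph", function(object) {
  mn <- object@metanodes
  me <- object@metaedges
  msgs <- character()
  need <- c("identifier", "abbreviation")
  if (!all(need %in% names(mn))) {
    return("metanodes must have columns 'identifier' and 'abbreviation'")
  }
  if (nrow(mn) == 0L) msgs <- c(msgs, "a metagraph needs at least one metanode")
  if (any(!nzchar(mn$abbreviation)) || any(!nzchar(mn$identifier))) {
    msgs <- c(msgs, "metanode identifiers and abbreviations must be non-empty")
  }
  if (anyDuplicated(mn$abbreviation)) msgs <- c(msgs, "metanode abbreviations must be unique")
  if (anyDuplicated(mn$identifier)) msgs <- c(msgs, "metanode identifiers must be unique")
  needE <- c("source", "target", "kind", "abbreviation", "directed")
  if (!all(needE %in% names(me))) {
    return("metaedges must have columns source, target, kind, abbreviation, directed")
  }
  if (nrow(me) > 0L) {
    if (!all(me$source %in% mn$abbreviation) || !all(me$target %in% mn$abbreviation)) {
      msgs <- c(msgs, "metaedge endpoints must be metanode abbreviations")
    }
    if (any(!nzchar(me$abbreviation))) msgs <- c(msgs, "metaedge abbreviations must be non-empty")
    key <- paste(me$source, me$abbreviation, me$target)
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "metaedge abbreviation must be unique per (source, target) pair")
    }
    full <- metaedgeAbbrev(me)
    if (anyDuplicated(full)) msgs <- c(msgs, "full metaedge abbreviations must be unique")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

# Full metaedge abbreviation, e.g. "CbG" or "Gr>G" for a directed metaedge.
metaedgeAbbrev <- function(me) {
  tok <- ifelse(me$directed, paste0(me$abbreviation, ">"), me$abbreviation)
  paste0(me$source, tok, me$target)
}

#' Construct a metagraph
#'
#' @param metanodes data.frame with columns \code{identifier}, \code{abbreviation}.
#' @param metaedges data.frame with columns \code{source}, \code{target},
#'   \code{kind}, \code{abbreviation} and optionally \code{directed}
#'   (defaults to \code{FALSE}).
#' @return A \linkS4class{Metagraph}.
#' @examples
#' mg <- metagraph(
#'   metanodes = data.frame(identifier = c("Compound", "Gene"),
#'                          abbreviation = c("C", "G")),
#'   metaedges = data.frame(source = "C", target = "G",
#'                          kind = "binds", abbreviation = "b")
#' )
#' @export
metagraph <- function(metanodes, metaedges) {
  metanodes <- as.data.frame(metanodes, stringsAsFactors = FALSE)
  metaedges <- as.data.frame(metaedges, stringsAsFactors = FALSE)
  if (is.null(metaedges$directed)) metaedges$directed <- FALSE
  metanodes <- metanodes[order(metanodes$abbreviation, method = "radix"), , drop = FALSE]
  rownames(metanodes) <- NULL
  rownames(metaedges) <- NULL
  new("Metagraph", metanodes = metanodes, metaedges = metaedges)
}

#' @describeIn metagraph Metanode table accessor.
#' @param x,object a \linkS4class{Metagraph}.
#' @export
setGeneric("metanodes", function(x) standardGeneric("metanodes"))

#' @rdname metagraph
#' @export
setMethod("metanodes", "Metagraph", function(x) x@metanodes)

#' @describeIn metagraph Metaedge table accessor (with a derived
#'   \code{abbrev} column holding the full abbreviation, e.g. \code{"CbG"}).
#' @export
setGeneric("metaedges", function(x) standardGeneric("metaedges"))

#' @rdname metagraph
#' @export
setMethod("metaedges", "Metagraph", function(x) {
  me <- x@metaedges
  me$abbrev <- if (nrow(me)) metaedgeAbbrev(me) else character()
  me
})

setMethod("show", "Metagraph", function(object) {
  cat(sprintf("Metagraph with %d metanodes and %d metaedges\n",
              nrow(object@metanodes), nrow(object@metaedges)))
  cat("  metanodes:", paste(object@metanodes$abbreviation, collapse = ", "), "\n")
  if (nrow(object@metaedges)) {
    cat("  metaedges:", paste(metaedgeAbbrev(object@metaedges), collapse = ", "), "\n")
  }
})

#' Read / write a metagraph schema as JSON
#'
#' The on-disk schema is a JSON object with fields \code{metanodes}
#' (identifier, abbreviation) and \code{metaedges} (source, target, kind,
#' abbreviation, directed).
#'
#' @param path file path to a metagraph JSON file.
#' @return \code{readMetagraph} returns a \linkS4class{Metagraph}.
#' @export
readMetagraph <- function(path) {
  if (!file.exists(path)) .stopf("hetpath_load_error", "metagraph file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$metanodes) || is.null(obj$metaedges)) {
    .stopf("hetpath_load_error", "metagraph JSON must contain 'metanodes' and 'metaedges': %s", path)
  }
  metagraph(obj$metanodes, obj$metaedges)
}

#' @rdname readMetagraph
#' @param mg a \linkS4class{Metagraph}.
#' @export
writeMetagraph <- function(mg, path) {
  stopifnot(is(mg, "Metagraph"))
  obj <- list(metanodes = mg@metanodes, metaedges = mg@metaedges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# index of a metanode abbreviation, with validation
.mnIndex <- function(mg, abbrev) {
  i <- match(abbrev, mg@metanodes$abbreviation)
  if (anyNA(i)) {
    .stopf("hetpath_key_error", "unknown metanode abbreviation: %s",
           paste(abbrev[is.na(i)], collapse = ", "))
  }
  i
}

# metaedge row index from a full abbreviation such as "CbG" or "Gr>G"
.meIndex <- function(mg, abbrev) {
  full <- metaedgeAbbrev(mg@metaedges)
  i <- match(abbrev, full)
  if (anyNA(i)) {
    .stopf("hetpath_key_error", "unknown metaedge abbreviation: %s",
           paste(abbrev[is.na(i)], collapse = ", "))
  }
  i
}
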