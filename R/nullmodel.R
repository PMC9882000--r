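# Degree-grouped null model for DWPCs.
#
# DWPCs computed on permuted hetnets form the null.  Because XSwap
# preserves degree, permuted DWPCs for all node pairs sharing the same
# (source degree, target degree) are exchangeable and are pooled into one
# degree group, which greatly inflates the effective number of
# permutations.  Per (metapath, source degree, target degree) we keep five
# additive running totals: number of null DWPCs, number of nonzero null
# DWPCs, their sum, their sum of squares, and the number of permuted
# hetnets contributed.  These suffice to fit a gamma-hurdle null
# (probability 1 - lambda at zero, gamma(alpha, beta) above it) or to fall
# back to an empirical p-value.

.statsCols <- c("metapath", "source_degree", "target_degree", "n_dwpcs",
                "n_nonzero_dwpcs", "sum", "sum_of_squares", "n_perms")

.emptyStats <- function() {
  df <- data.frame(metapath = character(), source_degree = numeric(),
                   target_degree = numeric(), n_dwpcs = numeric(),
                   n_nonzero_dwpcs = numeric(), sum = numeric(),
                   sum_of_squares = numeric(), n_perms = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Degree-group key of a node pair
#'
#' The degree group of a (source, target) pair for a metapath is the pair
#' (source node's edge count of the metapath's first metaedge type, target
#' node's edge count of the last metaedge type), with orientation taken
#' into account.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param metapath a \linkS4class{Metapath} or abbreviation.
#' @param sourceNode,targetNode node identifiers of the metapath's source
#'   and target metanodes.
#' @return named numeric vector \code{c(source_degree, target_degree)}.
#' @export
degreeGroupKey <- function(store, metapath, sourceNode, targetNode) {
  if (is.character(metapath)) metapath <- .parseMetapath(store@metagraph, metapath)
  dd <- .endpointDegrees(store, metapath)
  si <- match(sourceNode, nodeIds(store, sourceMetanode(metapath)))
  ti <- match(targetNode, nodeIds(store, targetMetanode(metapath)))
  if (is.na(si)) {
    .stopf("hetpath_validation_error", "node %s is not a %s node",
           sourceNode, sourceMetanode(metapath))
  }
  if (is.na(ti)) {
    .stopf("hetpath_validation_error", "node %s is not a %s node",
           targetNode, targetMetanode(metapath))
  }
  c(source_degree = dd$source[si], target_degree = dd$target[ti])
}

# degree vectors of the first metaedge (source side) and last metaedge
# (target side) of a metapath, orientation-correct
.endpointDegrees <- function(store, mp) {
  L <- length(mp)
  dFirst <- metaedgeDegrees(store, mp@edges[1L], inverted = mp@inverted[1L])
  dLast <- metaedgeDegrees(store, mp@edges[L], inverted = mp@inverted[L])
  list(source = dFirst$source, target = dLast$target)
}

#' Accumulate null DWPC summary statistics from one permuted DWPC matrix
#'
#' Every matrix entry contributes to the degree group of its (row, column)
#' pair; groups record running totals that are additive across permuted
#' hetnets (see \code{\link{mergeNullStats}}).
#'
#' @param dwpcMat numeric matrix of DWPCs computed on a permuted hetnet.
#' @param sourceDegrees,targetDegrees degree vectors for the matrix rows /
#'   columns w.r.t. the metapath's first / last metaedge (identical for the
#'   permuted and base store, since permutation preserves degree).
#' @param metapath metapath abbreviation the statistics belong to.
#' @return data.frame with columns \code{metapath}, \code{source_degree},
#'   \code{target_degree}, \code{n_dwpcs}, \code{n_nonzero_dwpcs},
#'   \code{sum}, \code{sum_of_squares}, \code{n_perms}.
#' @export
accumulateNullStats <- function(dwpcMat, sourceDegrees, targetDegrees, metapath) {
  dwpcMat <- as.matrix(dwpcMat)
  if (nrow(dwpcMat) != length(sourceDegrees) || ncol(dwpcMat) != length(targetDegrees)) {
    .stopf("hetpath_validation_error",
           "degree vectors do not match matrix dimensions (%dx%d vs %d/%d)",
           nrow(dwpcMat), ncol(dwpcMat), length(sourceDegrees), length(targetDegrees))
  }
  v <- as.vector(dwpcMat)
  ds <- rep(sourceDegrees, times = ncol(dwpcMat))
  dt <- rep(targetDegrees, each = nrow(dwpcMat))
  g <- interaction(ds, dt, drop = TRUE, lex.order = TRUE)
  agg <- rowsum(cbind(n = 1, nz = as.numeric(v > 0), s = v, ss = v^2), g)
  lab <- do.call(rbind, strsplit(rownames(agg), ".", fixed = TRUE))
  out <- data.frame(metapath = metapath,
                    source_degree = as.numeric(lab[, 1L]),
                    target_degree = as.numeric(lab[, 2L]),
                    n_dwpcs = agg[, "n"],
                    n_nonzero_dwpcs = agg[, "nz"],
                    sum = agg[, "s"],
                    sum_of_squares = agg[, "ss"],
                    n_perms = 1,
                    stringsAsFactors = FALSE)
  out <- out[order(out$source_degree, out$target_degree), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge degree-grouped null statistics
#'
#' Fieldwise sums per (metapath, source degree, target degree) key; the
#' running totals are associative and commutative, so statistics can be
#' updated incrementally as permuted hetnets are processed.
#'
#' @param a,b data.frames as returned by \code{\link{accumulateNullStats}}
#'   (possibly covering several metapaths).
#' @return merged data.frame.
#' @export
mergeNullStats <- function(a, b) {
  if (is.null(a) || nrow(a) == 0L) return(if (is.null(b)) .emptyStats() else b)
  if (is.null(b) || nrow(b) == 0L) return(a)
  both <- rbind(a[.statsCols], b[.statsCols])
  g <- interaction(both$metapath, both$source_degree, both$target_degree,
                   drop = TRUE, lex.order = TRUE)
  first <- !duplicated(g)
  agg <- rowsum(as.matrix(both[c("n_dwpcs", "n_nonzero_dwpcs", "sum",
                                 "sum_of_squares", "n_perms")]), g)
  keys <- both[first, c("metapath", "source_degree", "target_degree")]
  keys <- keys[match(rownames(agg), as.character(g[first])), , drop = FALSE]
  out <- cbind(keys, as.data.frame(agg))
  out <- out[order(out$metapath, out$source_degree, out$target_degree), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Null DWPC summary statistics over permuted hetnets
#'
#' Generates \code{nPerm} XSwap permutations of \code{store} and
#' accumulates degree-grouped null DWPC statistics for each metapath.
#'
#' @param store a \linkS4class{Hetnet}.
#' @param metapaths list of \linkS4class{Metapath} objects or character
#'   abbreviations.
#' @param nPerm number of permuted hetnets.
#' @param seed base seed; permutation \code{i} uses \code{seed + i - 1}.
#' @param multiplier XSwap attempts per edge.
#' @param w damping exponent for the null DWPCs.
#' @return data.frame of running totals (see
#'   \code{\link{accumulateNullStats}}).
#' @export
computeNullStats <- function(store, metapaths, nPerm = 50, seed = 0L,
                             multiplier = 10, w = 0.5) {
  if (is.character(metapaths)) metapaths <- as.list(metapaths)
  mps <- lapply(metapaths, function(m) {
    if (is.character(m)) .parseMetapath(store@metagraph, m) else m
  })
  total <- .emptyStats()
  degs <- lapply(mps, function(mp) .endpointDegrees(store, mp))
  generatePermutations(store, nPerm, baseSeed = seed, multiplier = multiplier,
                       callback = function(perm, i) {
    acc <- .emptyStats()
    for (j in seq_along(mps)) {
      mat <- dwpcMatrix(dwpc(perm, mps[[j]], w = w))
      acc <- mergeNullStats(acc, accumulateNullStats(
        mat, degs[[j]]$source, degs[[j]]$target, abbreviation(mps[[j]])))
    }
    total <<- mergeNullStats(total, acc)
  })
  total
}

#' Fit a gamma-hurdle distribution to degree-group statistics
#'
#' Method-of-moments estimators: \eqn{\hat\lambda = n/N} (nonzero
#' probability), nonzero mean \eqn{\hat\mu = \Sigma x / n}, Bessel-corrected
#' nonzero variance \eqn{\hat\sigma^2 = (n \Sigma x^2 - (\Sigma x)^2) /
#' (n(n-1))}, shape \eqn{\hat\alpha = \hat\mu^2/\hat\sigma^2} and rate
#' \eqn{\hat\beta = \hat\mu/\hat\sigma^2}.
#'
#' @param N total number of null DWPCs in the group.
#' @param n number of nonzero null DWPCs.
#' @param sum,sumSq sum and sum of squares of the nonzero null DWPCs.
#' @return list with \code{lambda}, \code{alpha}, \code{beta}, or
#'   \code{NULL} (a fallback signal, not an error) when the gamma part
#'   cannot be fit (\code{n < 2}, zero variance, or \code{N = 0}).
#' @examples
#' fitGammaHurdle(N = 6, n = 3, sum = 6, sumSq = 14)  # lambda .5, alpha 4, beta 2
#' @export
fitGammaHurdle <- function(N, n, sum, sumSq) {
  if (N <= 0 || n < 2) return(NULL)
  sigma2 <- (n * sumSq - sum^2) / (n * (n - 1))
  mu <- sum / n
  if (!is.finite(sigma2) || sigma2 <= .Machine$double.eps * mu^2) return(NULL)
  list(lambda = n / N, alpha = mu^2 / sigma2, beta = mu / sigma2)
}

#' Gamma-hurdle tail probability
#'
#' \eqn{P(X \ge t)} under the hurdle model: 1 for \eqn{t = 0} (the whole
#' support) and \eqn{\lambda Q(\alpha, \beta t)} for \eqn{t > 0}, where Q
#' is the regularized upper incomplete gamma function.  Note the
#' \eqn{\lambda} factor: the zero mass \eqn{1 - \lambda} never exceeds a
#' positive threshold, so the tail beyond any \eqn{t > 0} is carried by the
#' gamma component alone.
#'
#' @param t observed DWPC (non-negative).
#' @param params list with \code{lambda}, \code{alpha}, \code{beta} (as
#'   from \code{\link{fitGammaHurdle}}), or the three values given
#'   separately.
#' @param lambda,alpha,beta used when \code{params} is missing.
#' @return the p-value in [0, 1].
#' @export
gammaHurdlePvalue <- function(t, params = NULL, lambda = NULL, alpha = NULL,
                              beta = NULL) {
  if (!is.null(params)) {
    lambda <- params$lambda; alpha <- params$alpha; beta <- params$beta
  }
  if (is.null(lambda) || is.null(alpha) || is.null(beta) ||
      !is.finite(lambda) || lambda < 0 || lambda > 1 ||
      !is.finite(alpha) || alpha <= 0 || !is.finite(beta) || beta <= 0) {
    .stopf("hetpath_validation_error", "invalid gamma-hurdle parameters")
  }
  if (any(t < 0)) .stopf("hetpath_validation_error", "t must be non-negative")
  ifelse(t == 0, 1, lambda * pgamma(t, shape = alpha, rate = beta, lower.tail = FALSE))
}

#' Empirical DWPC p-value from summary statistics
#'
#' Fallback for degree groups where the gamma part cannot be fit, using
#' only the stored running totals:
#' \itemize{
#'   \item observed DWPC \eqn{t = 0}: p = 1 (no paths existed);
#'   \item all null DWPCs zero but \eqn{t > 0}: p = 0;
#'   \item all nonzero null DWPCs equal one value \eqn{v} (sd = 0): p = 0
#'     if \eqn{t > v}, else the proportion of nonzero null DWPCs \eqn{n/N}.
#' }
#'
#' @inheritParams fitGammaHurdle
#' @param t observed DWPC.
#' @return the empirical p-value.
#' @export
empiricalPvalue <- function(t, N, n, sum, sumSq) {
  if (t < 0) .stopf("hetpath_validation_error", "t must be non-negative")
  if (t == 0) return(1)
  if (n == 0) return(0)
  v <- sum / n
  sigma2 <- if (n >= 2) (n * sumSq - sum^2) / (n * (n - 1)) else 0
  if (sigma2 > .Machine$double.eps * v^2) {
    .stopf("hetpath_validation_error",
           "empirical p-value is only defined for degenerate null summaries; fit the gamma-hurdle instead")
  }
  if (t > v * (1 + 1e-9)) 0 else n / N
}

#' DWPC p-value with gamma-hurdle / empirical routing
#'
#' Fits the gamma-hurdle when the group has at least two distinct nonzero
#' null DWPCs; otherwise falls back to the empirical rules.  The method
#' used is recorded, along with the nonzero null mean and (when defined)
#' standard deviation.
#'
#' @param t observed DWPC.
#' @param N,n,sum,sumSq degree-group running totals; alternatively pass a
#'   one-row \code{stats} data.frame from \code{\link{computeNullStats}}.
#' @param stats optional one-row data.frame with columns \code{n_dwpcs},
#'   \code{n_nonzero_dwpcs}, \code{sum}, \code{sum_of_squares}.
#' @return list with \code{p_value}, \code{method} (\code{"gamma-hurdle"}
#'   or \code{"empirical"}), \code{nonzero_mean}, \code{nonzero_sd}.
#' @export
dwpcPvalue <- function(t, N = NULL, n = NULL, sum = NULL, sumSq = NULL,
                       stats = NULL) {
  if (!is.null(stats)) {
    N <- stats$n_dwpcs; n <- stats$n_nonzero_dwpcs
    sum <- stats$sum; sumSq <- stats$sum_of_squares
  }
  fit <- fitGammaHurdle(N, n, sum, sumSq)
  nzMean <- if (n >= 1) sum / n else NA_real_
  nzSd <- if (n >= 2) sqrt(max(0, (n * sumSq - sum^2) / (n * (n - 1)))) else NA_real_
  if (!is.null(fit)) {
    list(p_value = gammaHurdlePvalue(t, fit), method = "gamma-hurdle",
         nonzero_mean = nzMean, nonzero_sd = nzSd)
  } else {
    list(p_value = empiricalPvalue(t, N, n, sum, sumSq), method = "empirical",
         nonzero_mean = nzMean, nonzero_sd = nzSd)
  }
}

#' Bonferroni adjustment by metanode pair and metapath length
#'
#' Multiplies the p-value by the number of metapaths of the same length
#' between the source and target metanodes (under the reverse-deduplicated
#' enumeration convention) and caps at 1.
#'
#' @param p raw p-value in [0, 1].
#' @param mg a \linkS4class{Metagraph}.
#' @param sourceMetanode,targetMetanode metanode abbreviations.
#' @param length metapath length (number of steps).
#' @return adjusted p-value in [0, 1].
#' @export
bonferroniAdjust <- function(p, mg, sourceMetanode, targetMetanode, length) {
  if (any(p < 0 | p > 1)) .stopf("hetpath_validation_error", "p must be in [0, 1]")
  m <- .metapathCountBetween(mg, sourceMetanode, targetMetanode, length)
  if (m == 0L) {
    .stopf("hetpath_validation_error",
           "no metapaths of length %d between %s and %s", length,
           sourceMetanode, targetMetanode)
  }
  pmin(1, p * m)
}

#' Write / read null DWPC summary statistics
#'
#' One gzipped TSV per metapath with columns \code{source_degree},
#' \code{target_degree}, \code{n_dwpcs}, \code{n_nonzero_dwpcs},
#' \code{sum}, \code{sum_of_squares}, \code{n_perms}.
#'
#' @param stats data.frame from \code{\link{computeNullStats}}.
#' @param dir output directory.
#' @return \code{readNullStats} returns the combined data.frame.
#' @export
writeNullStats <- function(stats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mp in unique(stats$metapath)) {
    sub <- stats[stats$metapath == mp, setdiff(.statsCols, "metapath")]
    con <- gzfile(file.path(dir, paste0(mp, ".tsv.gz")), "wt")
    utils::write.table(sub, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' @rdname writeNullStats
#' @export
readNullStats <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv\\.gz$", full.names = TRUE)
  out <- lapply(files, function(f) {
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    df$metapath <- sub("\\.tsv\\.gz$", "", basename(f))
    df[.statsCols]
  })
  res <- do.call(rbind, out)
  if (is.null(res)) .emptyStats() else res
}
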