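# Shared generators for randomized tests.  All randomness is derived from
# explicit seeds so failures are reproducible.

# A random metagraph with nMetanodes node types and up to maxMetaedges
# metaedges (same-metanode undirected/directed metaedges included).
randomMetagraphSpec <- function(seed, nMetanodes = NULL, maxMetaedges = 4,
                                nodeRange = c(6L, 14L),
                                densityRange = c(0.08, 0.3)) {
  set.seed(seed)
  if (is.null(nMetanodes)) nMetanodes <- sample(2:4, 1)
  ab <- LETTERS[seq_len(nMetanodes)]
  counts <- sample(nodeRange[1]:nodeRange[2], nMetanodes, replace = TRUE)
  nME <- sample(2:maxMetaedges, 1)
  kinds <- letters[1:10]
  mes <- list()
  used <- character()
  tries <- 0
  while (length(mes) < nME && tries < 50) {
    tries <- tries + 1
    src <- sample(ab, 1)
    tgt <- sample(ab, 1)
    kind <- sample(kinds, 1)
    key <- paste(src, kind, tgt)
    rkey <- paste(tgt, kind, src)
    if (key %in% used || rkey %in% used) next
    used <- c(used, key)
    directed <- src == tgt && runif(1) < 0.3
    mes[[length(mes) + 1]] <- list(
      source = src, target = tgt, kind = kind, abbreviation = kind,
      directed = directed, density = runif(1, densityRange[1], densityRange[2]))
  }
  list(metanodes = data.frame(identifier = paste0("Type", ab), abbreviation = ab,
                              count = counts),
       metaedges = mes, seed = seed)
}

randomHetnet <- function(seed, ...) makeFixture(randomMetagraphSpec(seed, ...))

# expect two matrices to agree entrywise
expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol + 1e-300)
}
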