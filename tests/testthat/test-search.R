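# Path-level scoring and the end-to-end connectivity search.

test_that("path degree products match hand evaluation", {
  expect_equal(pathDegreeProduct(toyT2prime(), c("c2", "d1", "c1", "d2"),
                                 "CtDtCtD", w = 0.5), 0.25, tolerance = 1e-12)
  expect_equal(pathDegreeProduct(toyT1(), c("g1", "g2", "g3"), "GiGiG", w = 0.5),
               0.25, tolerance = 1e-12)
  # w = 0 gives 1 for any valid path
  expect_equal(pathDegreeProduct(toyT1(), c("g1", "g2", "g3"), "GiGiG", w = 0), 1)
  # invalid paths are rejected
  expect_error(pathDegreeProduct(toyT1(), c("g1", "g2", "g1"), "GiGiG", 0.5),
               "revisits", class = "hetpath_validation_error")
  expect_error(pathDegreeProduct(toyT2(), c("c1", "g3"), "CbG", 0.5),
               class = "hetpath_validation_error")
})

test_that("path enumeration decomposes the DWPC entry", {
  st <- toyT1()
  pp <- enumeratePaths(st, "g1", "g3", "GiGiG", w = 0.5)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$path, "g1 - g2 - g3")
  expect_equal(pp$percent_of_dwpc, 1)
  expect_equal(pp$pdp, dwpcMatrix(dwpc(st, "GiGiG", 0.5))["g1", "g3"])
  # no paths -> empty table, matching a zero DWPC entry (g3 is isolated)
  t2 <- toyT2()
  expect_equal(nrow(enumeratePaths(t2, "c2", "g3", "CbGbCbG", w = 0.5)), 0L)
  expect_equal(dwpcMatrix(dwpc(t2, "CbGbCbG", 0.5))["c2", "g3"], 0)
  # sum of path degree products equals the matrix DWPC on random fixtures
  for (seed in c(81, 82, 83)) {
    stR <- randomHetnet(seed)
    df <- enumerateMetapaths(stR@metagraph, 3, as = "data.frame")
    for (a in df$abbreviation[seq_len(min(8, nrow(df)))]) {
      mp <- metapath(stR@metagraph, a)
      d <- dwpcMatrix(dwpc(stR, mp, w = 0.5))
      srcs <- nodeIds(stR, sourceMetanode(mp))
      tgts <- nodeIds(stR, targetMetanode(mp))
      set.seed(seed)
      for (i in sample(length(srcs), min(3, length(srcs)))) {
        for (j in sample(length(tgts), min(3, length(tgts)))) {
          pp <- enumeratePaths(stR, srcs[i], tgts[j], mp, w = 0.5)
          expect_equal(sum(pp$pdp), d[srcs[i], tgts[j]], tolerance = 1e-10)
          if (nrow(pp) > 0) expect_equal(sum(pp$percent_of_dwpc), 1, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("path scores follow percent * -log10(p) with a cap at p = 0", {
  expect_equal(pathScore(1, 0.01), 2)
  expect_equal(pathScore(0.5, 1e-4), 2)
  expect_equal(pathScore(0.7, 1), 0)
  expect_equal(pathScore(0.5, 0), 160)  # capped at -log10 p = 320
  expect_error(pathScore(1.2, 0.5), class = "hetpath_validation_error")
})

test_that("storage thresholds implement the node-count penalty", {
  expect_identical(storageThreshold(10, 10, 1), Inf)  # length 1: keep all nonzero
  expect_equal(storageThreshold(1, 1, 2), 5)
  expect_equal(storageThreshold(20945, 20945, 2), 5 * (20945^2)^(-0.3))
  expect_equal(storageThreshold(20945, 20945, 3), 0.01277, tolerance = 1e-3)
  expect_equal(storageThreshold(137, 1822, 2), 0.1202, tolerance = 1e-3)
})

test_that("connectivity search ranks a planted metapath first", {
  planted <- function(seed) {
    spec <- list(
      metanodes = data.frame(identifier = c("Compound", "Disease", "Gene"),
                             abbreviation = c("C", "D", "G"), count = c(20, 15, 30)),
      metaedges = list(
        list(source = "C", target = "G", kind = "binds", abbreviation = "b", density = 0.08),
        list(source = "D", target = "G", kind = "associates", abbreviation = "a", density = 0.08),
        list(source = "C", target = "D", kind = "treats", abbreviation = "t", density = 0.05),
        list(source = "C", target = "C", kind = "resembles", abbreviation = "r", density = 0.05)),
      seed = seed)
    st <- makeFixture(spec)
    bg <- as.matrix(adjacencyMatrix(st, "CbG"))
    ag <- as.matrix(adjacencyMatrix(st, "DaG"))
    bg[1, 1:6] <- 1   # c001 binds six genes ...
    ag[1, 1:6] <- 1   # ... all associated with d001
    hetnet(st@metagraph, st@nodes,
           list(CbG = bg, DaG = ag, CtD = adjacencyMatrix(st, "CtD"),
                CrC = adjacencyMatrix(st, "CrC")))
  }
  st <- planted(301)
  df <- enumerateMetapaths(st@metagraph, 2, as = "data.frame")
  df <- df[(df$source == "C" & df$target == "D") |
             (df$source == "D" & df$target == "C"), ]
  nulls <- computeNullStats(st, df$abbreviation, nPerm = 25, seed = 401)
  res <- connectivitySearch(st, nulls, "c001", "d001", maxLength = 2)
  expect_identical(res$metapaths$metapath[1], "CbGaD")
  # row invariants
  m <- res$metapaths
  expect_setequal(names(m), c("metapath", "path_count", "dwpc", "p_value",
                              "adjusted_p_value", "source_degree", "target_degree",
                              "n_dwpcs", "n_nonzero_dwpcs", "nonzero_mean", "nonzero_sd"))
  expect_true(all((m$path_count == 0) == (m$dwpc == 0)))
  expect_true(all(m$p_value[m$dwpc == 0] == 1))
  expect_true(all(m$adjusted_p_value >= m$p_value))
  expect_true(!is.unsorted(m$adjusted_p_value))
  # adjusted p equals the Bonferroni adjustment at the correct count
  for (r in seq_len(nrow(m))) {
    expect_equal(m$adjusted_p_value[r],
                 bonferroniAdjust(m$p_value[r], st@metagraph, "C", "D",
                                  length(metapath(st@metagraph, m$metapath[r]))))
  }
  # paths are sorted by score and cover the planted metapath
  expect_true(!is.unsorted(-res$paths$path_score))
  expect_true("CbGaD" %in% res$paths$metapath)

  # swapping the query nodes reverses abbreviations but preserves content
  res2 <- connectivitySearch(st, nulls, "d001", "c001", maxLength = 2)
  revAb <- vapply(res2$metapaths$metapath, function(a)
    abbreviation(reverse(metapath(st@metagraph, a))), character(1))
  expect_setequal(unname(revAb), m$metapath)
  expect_equal(res2$metapaths$p_value[match(m$metapath, revAb)], m$p_value)
  expect_equal(res2$metapaths$source_degree[match(m$metapath, revAb)],
               m$target_degree)

  # unknown node identifiers give a lookup error with suggestions
  expect_error(connectivitySearch(st, nulls, "c01", "d001", maxLength = 2),
               "did you mean", class = "hetpath_lookup_error")
})

test_that("search on an edgeless store returns all-null rows", {
  mg <- toyT2prime()@metagraph
  st <- hetnet(mg, list(C = c("c1", "c2"), D = c("d1", "d2")))
  df <- enumerateMetapaths(mg, 2, as = "data.frame")
  df <- df[(df$source == "C" & df$target == "D") |
             (df$source == "D" & df$target == "C"), ]
  nulls <- computeNullStats(st, df$abbreviation, nPerm = 2, seed = 1)
  res <- connectivitySearch(st, nulls, "c1", "d1", maxLength = 2)
  expect_true(all(res$metapaths$path_count == 0))
  expect_true(all(res$metapaths$p_value == 1))
  expect_equal(nrow(res$paths), 0L)
})

test_that("the storage filter keeps only significant nonzero rows", {
  st <- toyT2prime()
  nulls <- computeNullStats(st, "CtD", nPerm = 5, seed = 2)
  res <- connectivitySearch(st, nulls, "c1", "d1", maxLength = 1,
                            applyStorageFilter = TRUE)
  # length-1 metapaths store all nonzero DWPCs regardless of significance
  expect_true(all(res$metapaths$dwpc > 0))
})
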