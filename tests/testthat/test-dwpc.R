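# DWPC computation: correction formulas, matrix-vs-enumeration oracle
# equivalence, and the approximate method.

test_that("triangle fixture gives the hand-computed DWPC and path counts", {
  st <- toyT1()
  d <- dwpcMatrix(dwpc(st, "GiGiG", w = 0.5))
  expect_equal(unname(Matrix::diag(d)), rep(0, 3))
  expect_equal(unname(d[upper.tri(d) | lower.tri(d)]), rep(0.25, 6))
  pc <- dwpc(st, "GiGiG", w = 0)
  expect_identical(pc@kind, "path-count")
  expect_equal(unname(dwpcMatrix(pc)),
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  # length-3 same-metanode repeat (4 occurrences): no simple path in K3
  expect_equal(max(dwpcMatrix(dwpc(st, "GiGiGiG", w = 0))), 0)
})

test_that("overlapping-repeat fixture matches the hand enumeration", {
  st <- toyT2prime()
  d <- dwpcMatrix(dwpc(st, "CtDtCtD", w = 0.5))
  expect_equal(d["c2", "d2"], 0.25, tolerance = 1e-12)
  expect_equal(d["c1", "d1"], 0)
  expect_equal(d["c1", "d2"], 0)
  expect_equal(d["c2", "d1"], 0)
})

test_that("correction operators implement the stated formulas", {
  # short repeat: product minus its diagonal, on the triangle's damped
  # adjacency (off-diagonal 0.5): product has diagonal 0.5 / off-diagonal
  # 0.25, so the corrected result has diagonal 0 and off-diagonal 0.25
  D <- matrix(0.5, 3, 3); diag(D) <- 0
  got <- dwpcShortRepeat(D, D)
  expect_equal(unname(diag(got)), rep(0, 3))
  expect_equal(unname(got[upper.tri(got) | lower.tri(got)]), rep(0.25, 6))
  expect_equal(dwpcShortRepeat(D * 0, D * 0), matrix(0, 3, 3))
  expect_error(dwpcShortRepeat(D, matrix(0, 2, 2)), class = "hetpath_validation_error")
  # nested: triple product minus its diagonal; zero inner matrix kills it
  Dxy <- matrix(runif(6), 2, 3)
  Dyy <- matrix(runif(9), 3, 3); diag(Dyy) <- 0
  expect_equal(dwpcNested(Dxy, Dyy * 0, t(Dxy)), matrix(0, 2, 2))
  out <- dwpcNested(Dxy, Dyy, t(Dxy))
  expect_equal(unname(diag(out)), c(0, 0))
  # overlapping: all-zero inputs give zero
  expect_equal(dwpcOverlapping(Dxy * 0, t(Dxy) * 0, Dxy * 0), matrix(0, 2, 3))
})

test_that("specialized formulas equal the enumeration oracle on random graphs", {
  # short repeat XaXbX over one metanode
  for (seed in 1:10) {
    spec <- list(
      metanodes = data.frame(identifier = "TypeA", abbreviation = "A", count = 10),
      metaedges = list(list(source = "A", target = "A", kind = "i",
                            abbreviation = "i", density = 0.3)),
      seed = seed)
    st <- makeFixture(spec)
    expect_matrix_equal(dwpcMatrix(dwpc(st, "AiAiA", w = 0.5)),
                        dwpcMatrix(dwpc(st, "AiAiA", w = 0.5, method = "enumeration")))
  }
  # nested XaYbYcX and overlapping XaYbXcY over two metanodes
  for (seed in 11:25) {
    spec <- list(
      metanodes = data.frame(identifier = c("TypeX", "TypeY"),
                             abbreviation = c("X", "Y"), count = c(8, 9)),
      metaedges = list(
        list(source = "X", target = "Y", kind = "t", abbreviation = "t", density = 0.25),
        list(source = "Y", target = "Y", kind = "r", abbreviation = "r", density = 0.25)),
      seed = seed)
    st <- makeFixture(spec)
    for (a in c("XtYrYtX", "XtYtXtY")) {
      expect_matrix_equal(dwpcMatrix(dwpc(st, a, w = 0.5)),
                          dwpcMatrix(dwpc(st, a, w = 0.5, method = "enumeration")))
    }
  }
})

test_that("w = 0 matrices are integral simple-path counts", {
  for (seed in c(61, 62, 63)) {
    st <- randomHetnet(seed)
    df <- enumerateMetapaths(st@metagraph, 3, as = "data.frame")
    for (a in df$abbreviation[seq_len(min(25, nrow(df)))]) {
      m <- dwpcMatrix(dwpc(st, a, w = 0))
      expect_equal(m, round(m))
      expect_true(all(m >= 0))
    }
  }
})

test_that("reversal transposes the DWPC matrix", {
  st <- randomHetnet(64)
  df <- enumerateMetapaths(st@metagraph, 3, as = "data.frame")
  for (a in df$abbreviation[seq_len(min(20, nrow(df)))]) {
    mp <- metapath(st@metagraph, a)
    expect_matrix_equal(dwpcMatrix(dwpc(st, reverse(mp), w = 0.5)),
                        t(dwpcMatrix(dwpc(st, mp, w = 0.5))))
  }
})

test_that("DWPC is entrywise non-increasing in the damping exponent", {
  # all degrees >= 1 so that every damping factor is <= 1
  spec <- list(
    metanodes = data.frame(identifier = c("TypeA", "TypeB"),
                           abbreviation = c("A", "B"), count = c(8, 8)),
    metaedges = list(list(source = "A", target = "B", kind = "x",
                          abbreviation = "x",
                          degrees = list(source = rep(3L, 8), target = rep(3L, 8)))),
    seed = 65)
  st <- makeFixture(spec)
  prev <- dwpcMatrix(dwpc(st, "AxBxAxB", w = 0))
  for (w in c(0.25, 0.5, 0.75, 1)) {
    cur <- dwpcMatrix(dwpc(st, "AxBxAxB", w = w))
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("an edgeless store yields zero matrices for any method", {
  mg <- toyT2()@metagraph
  st <- hetnet(mg, list(C = c("c1", "c2"), G = c("g1", "g2", "g3")))
  for (method in c("matrix", "enumeration", "approximate")) {
    expect_equal(max(dwpcMatrix(dwpc(st, "CbGbCbG", w = 0.5, method = method))), 0)
  }
})

test_that("caching is semantically invisible and unsupported methods error", {
  st <- randomHetnet(66)
  df <- enumerateMetapaths(st@metagraph, 3, as = "data.frame")
  for (a in df$abbreviation[seq_len(min(15, nrow(df)))]) {
    expect_identical(dwpcMatrix(dwpc(st, a, w = 0.5, cache = TRUE)),
                     dwpcMatrix(dwpc(st, a, w = 0.5, cache = FALSE)))
  }
  # cached segments are reused across metapaths sharing a prefix
  expect_gt(length(ls(st@cache)), 0L)
  expect_error(dwpc(st, df$abbreviation[1], method = "banana"),
               class = "hetpath_validation_error")
})

test_that("enumeration budget raises a resource error naming the budget", {
  st <- toyT1()
  expect_error(dwpc(st, "GiGiG", w = 0.5, method = "enumeration", budget = 3),
               "budget", class = "hetpath_budget_error")
})

test_that("approximate method is exact without complex segments and bounds above otherwise", {
  st <- randomHetnet(67)
  df <- enumerateMetapaths(st@metagraph, 4, as = "data.frame")
  exactCats <- df$abbreviation[df$category != "complex"]
  for (a in exactCats[seq_len(min(15, length(exactCats)))]) {
    r <- dwpc(st, a, w = 0.5, method = "approximate")
    expect_false(r@approximate)
    expect_matrix_equal(dwpcMatrix(r), dwpcMatrix(dwpc(st, a, w = 0.5)))
  }
  complexCats <- df$abbreviation[df$category == "complex"]
  for (a in complexCats[seq_len(min(15, length(complexCats)))]) {
    appr <- dwpcMatrix(dwpc(st, a, w = 0.5, method = "approximate"))
    exact <- dwpcMatrix(dwpc(st, a, w = 0.5, method = "enumeration"))
    # approximation never removes valid paths, so it bounds from above
    expect_true(all(appr - exact >= -1e-10))
  }
})
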