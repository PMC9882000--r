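# Degree-grouped null statistics, the gamma-hurdle fit, p-values with
# empirical fallbacks, and the Bonferroni adjustment.

test_that("degree-group keys use the first/last metaedge with orientation", {
  t2 <- toyT2()
  expect_equal(degreeGroupKey(t2, "CbG", "c1", "g2"),
               c(source_degree = 2, target_degree = 2))
  expect_equal(degreeGroupKey(t2, "CbG", "c2", "g3"),
               c(source_degree = 1, target_degree = 0))
  # reversal swaps the roles
  mg <- t2@metagraph
  expect_equal(unname(degreeGroupKey(t2, reverse(metapath(mg, "CbG")), "g2", "c1")),
               c(2, 2))
  expect_error(degreeGroupKey(t2, "CbG", "g1", "g2"), class = "hetpath_validation_error")
})

test_that("accumulation reproduces the hand-computed group totals", {
  m <- matrix(c(0, 0.5, 0.25, 0.25), nrow = 2, byrow = TRUE)  # [[0,.5],[.25,.25]]
  st <- accumulateNullStats(m, c(1, 1), c(1, 1), "XxY")
  expect_equal(nrow(st), 1L)
  expect_equal(st$n_dwpcs, 4)
  expect_equal(st$n_nonzero_dwpcs, 3)
  expect_equal(st$sum, 1)
  expect_equal(st$sum_of_squares, 0.375)
  expect_equal(st$n_perms, 1)
  # all-zero matrix: zero sums, group sizes still conserved
  z <- accumulateNullStats(matrix(0, 3, 2), c(1, 2, 1), c(4, 4), "XxY")
  expect_equal(sum(z$n_dwpcs), 6)
  expect_equal(sum(z$n_nonzero_dwpcs), 0)
  expect_equal(sum(z$sum), 0)
  expect_error(accumulateNullStats(m, c(1, 1, 1), c(1, 1), "XxY"),
               class = "hetpath_validation_error")
})

test_that("merge is an associative, commutative fieldwise sum", {
  set.seed(89)
  m1 <- matrix(runif(12), 3)
  m2 <- matrix(rbinom(12, 1, 0.4) * runif(12), 3)
  ds <- c(1, 2, 1); dt <- c(3, 3, 1, 2)
  a <- accumulateNullStats(m1, ds, dt, "XxY")
  b <- accumulateNullStats(m2, ds, dt, "XxY")
  joint <- accumulateNullStats(cbind(m1, m2), ds, c(dt, dt), "XxY")
  ab <- mergeNullStats(a, b)
  expect_equal(ab[c("source_degree", "target_degree", "n_dwpcs", "n_nonzero_dwpcs",
                    "sum", "sum_of_squares")],
               joint[c("source_degree", "target_degree", "n_dwpcs", "n_nonzero_dwpcs",
                       "sum", "sum_of_squares")])
  expect_equal(ab$n_perms, rep(2, nrow(ab)))
  expect_equal(mergeNullStats(a, b), mergeNullStats(b, a))
  expect_equal(mergeNullStats(mergeNullStats(a, b), a), mergeNullStats(a, mergeNullStats(b, a)))
  expect_equal(mergeNullStats(a, NULL), a)
  # Cauchy-Schwarz invariant on accumulated groups
  ok <- with(ab, n_nonzero_dwpcs * sum_of_squares + 1e-12 >= sum^2 |
               n_nonzero_dwpcs == 0)
  expect_true(all(ok))
})

test_that("method-of-moments fit matches the worked example and falls back", {
  fit <- fitGammaHurdle(N = 6, n = 3, sum = 6, sumSq = 14)
  expect_equal(fit$lambda, 0.5)
  expect_equal(fit$alpha, 4)
  expect_equal(fit$beta, 2)
  expect_null(fitGammaHurdle(N = 6, n = 1, sum = 2, sumSq = 4))    # Bessel undefined
  expect_null(fitGammaHurdle(N = 6, n = 3, sum = 6, sumSq = 12))   # zero variance
  expect_null(fitGammaHurdle(N = 0, n = 0, sum = 0, sumSq = 0))
})

test_that("parameters are recovered from simulated gamma-hurdle draws", {
  set.seed(90)
  n <- 1e5
  nonzero <- rbinom(n, 1, 0.6) == 1
  x <- numeric(n)
  x[nonzero] <- rgamma(sum(nonzero), shape = 3, rate = 2)
  fit <- fitGammaHurdle(N = n, n = sum(nonzero), sum = sum(x), sumSq = sum(x^2))
  expect_equal(fit$lambda, 0.6, tolerance = 0.05)
  expect_equal(fit$alpha, 3, tolerance = 0.05)
  expect_equal(fit$beta, 2, tolerance = 0.05)
})

test_that("gamma-hurdle tail has the exponential closed form and monotonicity", {
  p <- gammaHurdlePvalue(1, lambda = 0.5, alpha = 1, beta = 2)
  expect_equal(p, 0.5 * exp(-2), tolerance = 1e-12)
  expect_equal(gammaHurdlePvalue(0, lambda = 0.5, alpha = 1, beta = 2), 1)
  expect_lt(gammaHurdlePvalue(50, lambda = 0.5, alpha = 1, beta = 2), 1e-12)
  ts <- seq(0.01, 5, length.out = 50)
  ps <- gammaHurdlePvalue(ts, lambda = 0.8, alpha = 2.5, beta = 1.3)
  expect_true(all(diff(ps) < 0))  # strictly decreasing for t > 0
  expect_error(gammaHurdlePvalue(1, lambda = 1.5, alpha = 1, beta = 1),
               class = "hetpath_validation_error")
  expect_error(gammaHurdlePvalue(-1, lambda = 0.5, alpha = 1, beta = 1),
               class = "hetpath_validation_error")
})

test_that("empirical fallback implements the three summary-statistic rules", {
  # rule 1: observed DWPC of zero
  expect_equal(empiricalPvalue(0, N = 400, n = 17, sum = 3, sumSq = 1), 1)
  # rule 2: all null DWPCs zero, observed positive
  expect_equal(empiricalPvalue(0.3, N = 400, n = 0, sum = 0, sumSq = 0), 0)
  # rule 3: all nonzero nulls share one value (sd = 0)
  expect_equal(empiricalPvalue(0.2, N = 10, n = 4, sum = 0.8, sumSq = 0.16), 0.4)
  expect_equal(empiricalPvalue(0.25, N = 10, n = 4, sum = 0.8, sumSq = 0.16), 0)
})

test_that("dwpcPvalue routes between gamma-hurdle and empirical", {
  stats <- data.frame(n_dwpcs = 6, n_nonzero_dwpcs = 3, sum = 6, sum_of_squares = 14)
  r <- dwpcPvalue(1.5, stats = stats)
  expect_identical(r$method, "gamma-hurdle")
  expect_equal(r$p_value, gammaHurdlePvalue(1.5, fitGammaHurdle(6, 3, 6, 14)))
  expect_equal(r$nonzero_mean, 2)
  expect_equal(r$nonzero_sd, 1)
  r1 <- dwpcPvalue(1.5, N = 6, n = 1, sum = 2, sumSq = 4)
  expect_identical(r1$method, "empirical")
  expect_true(is.na(r1$nonzero_sd))
  # p stays in [0, 1] over random draws of stats and t
  set.seed(91)
  for (i in 1:2000) {
    n <- sample(0:5, 1)
    vals <- if (n > 0) rgamma(n, 2, 1) else numeric()
    N <- n + sample(0:5, 1)
    r <- dwpcPvalue(sample(c(0, rgamma(1, 1, 1)), 1),
                    N = N, n = n, sum = sum(vals), sumSq = sum(vals^2))
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("Bonferroni adjustment multiplies by the metapath count and caps", {
  mg <- hetionetMetagraph()
  # Disease..Pathway: 3 metapaths of length 2, so p of 5.9% triples
  expect_equal(bonferroniAdjust(0.059, mg, "D", "PW", 2), 0.177)
  expect_equal(bonferroniAdjust(0.02, mg, "D", "PW", 2) / 0.02, 3)
  expect_equal(bonferroniAdjust(0.5, mg, "D", "PW", 2), 1)  # capped
  expect_equal(bonferroniAdjust(0.02, mg, "D", "PW", 3) / 0.02, 24)
  expect_error(bonferroniAdjust(0.02, mg, "D", "PW", 1), class = "hetpath_validation_error")
  expect_error(bonferroniAdjust(1.2, mg, "D", "PW", 2), class = "hetpath_validation_error")
  # adjusted >= raw, equality iff one test or p = 0
  expect_equal(bonferroniAdjust(0, mg, "D", "PW", 2), 0)
})

test_that("null statistics round-trip through per-metapath TSV files", {
  st <- randomHetnet(92)
  df <- enumerateMetapaths(st@metagraph, 2, as = "data.frame")
  mps <- df$abbreviation[seq_len(min(3, nrow(df)))]
  nulls <- computeNullStats(st, mps, nPerm = 4, seed = 7)
  expect_true(all(nulls$n_perms == 4))
  dir <- tempfile("nulls")
  writeNullStats(nulls, dir)
  back <- readNullStats(dir)
  back <- back[order(back$metapath, back$source_degree, back$target_degree), ]
  rownames(back) <- NULL
  expect_equal(back, nulls[order(nulls$metapath, nulls$source_degree,
                                 nulls$target_degree), ],
               ignore_attr = TRUE, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
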