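test_that("constant tracks produce no EPODs", {
  expect_equal(length(callEpods(zTrack(rep(1, 4200)))), 0)
})

test_that("sub-minimum plateaus are rejected on an occupied chromosome", {
  # On a chromosome with a realistic (~10%) load of occupancy domains the
  # 90th-percentile threshold sits at the domain amplitude, so the rolling
  # window's spill-over around a strong 900-bp plateau stays under the
  # 1,024-bp seed minimum and the plateau is not called, while the 2-kb
  # domains are.
  n <- 20000; L <- n * 5
  starts2k <- c(1000, 5000, 9000, 13000, 17000)
  for (s in 1:5) {
    set.seed(s)
    v <- rnorm(n)
    for (st in starts2k) v[st:(st + 399)] <- v[st:(st + 399)] + 5
    v[3000:3179] <- v[3000:3179] + 5  # 180 bins = 900 bp
    ep <- callEpods(GenomeTrack(v, L, 5), epodParams(90))
    m900 <- GenomeFeatures(2999 * 5, 3180 * 5, L)
    covered <- if (length(ep) > 0) intervalOverlapFraction(m900, ep, L)$fracAinB else 0
    expect_lt(covered, 0.5)
    tr <- GenomeFeatures((starts2k - 1) * 5, (starts2k + 399) * 5, L)
    expect_gte(truthVsCalled(tr, ep)$jaccard, 0.8)
  }
})

test_that("a 2-kb plateau is recovered once with tight extension", {
  n <- 20000  # 100 kb
  v <- rep(0, n)
  v[5001:5400] <- 5  # 2,000 bp plateau
  set.seed(2)
  v <- v + rnorm(n, 0, 0.05)
  ep <- callEpods(zTrack(v), epodParams(90))
  expect_equal(length(ep), 1)
  expect_lte(ep@start, 5000 * 5)
  expect_gte(ep@end, 5400 * 5)
  # extends less than one window beyond the plateau on each side
  expect_gt(ep@start, 5000 * 5 - 512)
  expect_lt(ep@end, 5400 * 5 + 512)
})

test_that("the seed-and-extend caller equals the naive oracle", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(600:2000, 1)
    v <- rnorm(n, 0, 1)
    # plant 0-3 plateaus so many tracks have calls
    for (k in seq_len(sample(0:3, 1))) {
      w <- sample(150:400, 1)
      s <- sample(n - w, 1)
      v[s:(s + w)] <- v[s:(s + w)] + runif(1, 2, 5)
    }
    k <- sample(c(75, 90), 1)
    got <- callEpods(zTrack(v), epodParams(k))
    want <- naiveEpods(v, 5, k)
    if (is.null(want)) {
      expect_equal(length(got), 0, info = paste("case", i))
    } else {
      expect_equal(length(got), nrow(want), info = paste("case", i))
      expect_equal(featureStarts(got), want$start, info = paste("case", i))
      expect_equal(featureEnds(got), want$end, info = paste("case", i))
      expect_equal(featureScores(got), want$meanZ, tolerance = 1e-9,
                   info = paste("case", i))
    }
  }
})

test_that("strict calls are a base-pair subset of relaxed calls", {
  set.seed(4)
  for (i in 1:20) {
    n <- 20000
    v <- rnorm(n)
    for (k in 1:3) {
      w <- sample(300:900, 1); s <- sample(n - w, 1)
      v[s:(s + w)] <- v[s:(s + w)] + runif(1, 1.5, 4)
    }
    z <- zTrack(v)
    strict <- callEpods(z, epodParams(90))
    relaxed <- callEpods(z, epodParams(75))
    if (length(strict) > 0) {
      expect_equal(as.numeric(epodContainment(strict, relaxed)), 1.0,
                   info = paste("seed", i))
    }
  }
})

test_that("EPOD set comparison metrics are exact on constructions", {
  L <- 10000
  a <- GenomeFeatures(c(1000, 5000), c(2000, 6000), L)
  b <- GenomeFeatures(c(1500, 5000), c(2500, 6000), L)
  m <- epodOverlapMatrix(list(x = a, y = b), L)
  expect_equal(diag(m), c(x = 1, y = 1))
  expect_equal(m["x", "y"], m["y", "x"])
  expect_equal(m["x", "y"], 0.75)  # (1500/2000 + 1500/2000)/2
  expect_equal(epodOverlapMatrix(list(a = a, b = a), L)["a", "b"], 1.0)
  disj <- GenomeFeatures(8000, 9000, L)
  expect_equal(epodOverlapMatrix(list(a = a, b = disj), L)["a", "b"], 0.0)
  # containment
  expect_equal(as.numeric(epodContainment(a, a, L)), 1.0)
  expect_equal(as.numeric(epodContainment(a, b, L)), 0.75)
  e <- GenomeFeatures(genomeLength = L)
  r <- epodContainment(e, a, L)
  expect_equal(as.numeric(r), 0)
  expect_true(isTRUE(attr(r, "empty")))
})

test_that("feature enrichment inside EPODs is detected and calibrated", {
  n <- 10000; L <- n * 5
  ep <- GenomeFeatures(c(5000, 30000), c(6000, 31000), L)
  # feature = indicator of the EPODs themselves: maximal statistic, minimal p
  ind <- numeric(n)
  for (i in 1:2) ind[binsForInterval(ep@start[i], ep@end[i], zTrack(numeric(n)))] <- 1
  r <- epodFeatureEnrichment(ep, zTrack(ind), nPerm = 99, seed = 5)
  expect_gt(r$medianDiff, 0.9)
  expect_equal(r$p, 1 / 100)
  # constant feature: zero difference, p = 1
  r2 <- epodFeatureEnrichment(ep, zTrack(rep(2, n)), nPerm = 49, seed = 6)
  expect_equal(r2$medianDiff, 0)
  expect_equal(r2$p, 1.0)
  # unrelated random feature: observed statistic typical of the null
  set.seed(7)
  r3 <- epodFeatureEnrichment(ep, zTrack(rnorm(n)), nPerm = 99, seed = 8)
  expect_gt(r3$p, 0.01)
})
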