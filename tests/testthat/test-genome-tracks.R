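test_that("GenomeTrack enforces its bin-grid invariants", {
  expect_error(GenomeTrack(1:5, genomeLength = 100, resolution = 5),
               "ceiling")
  tr <- GenomeTrack(c(1, NA, 3), genomeLength = 15, resolution = 5)
  expect_equal(nBins(tr), 3)
  expect_error(GenomeTrack(c(1, Inf, 3), genomeLength = 15, resolution = 5),
               "finite")
  # last bin truncated when resolution does not divide the genome
  tr2 <- GenomeTrack(1:3, genomeLength = 13, resolution = 5)
  expect_equal(nBins(tr2), 3)
})

test_that("rolling mean matches hand computation and the naive oracle", {
  tr <- zTrack(c(0, 0, 10, 0, 0))
  out <- binValues(rollingMeanCircular(tr, 15))  # 3-bin window
  expect_equal(out, c(0, 10/3, 10/3, 10/3, 0))
  # constant track unchanged; mean conserved
  ct <- zTrack(rep(2.5, 40))
  expect_equal(binValues(rollingMeanCircular(ct, 35)), rep(2.5, 40))
  set.seed(42)
  for (w in c(2, 3, 7, 10)) {
    x <- rnorm(50)
    x[sample(50, 5)] <- NA
    tr <- zTrack(x)
    expect_equal(binValues(rollingMeanCircular(tr, w * 5)),
                 naiveRollingMean(x, w), tolerance = 1e-12)
  }
  # mean conservation without missing bins
  x <- rnorm(64)
  expect_equal(mean(binValues(rollingMeanCircular(zTrack(x), 45))), mean(x))
})

test_that("rolling mean is translation-equivariant on the circle", {
  set.seed(7)
  x <- rnorm(80)
  sm <- binValues(rollingMeanCircular(zTrack(x), 25))
  for (shift in c(1, 13, 40)) {
    xs <- c(x[-(seq_len(shift))], x[seq_len(shift)])
    sms <- binValues(rollingMeanCircular(zTrack(xs), 25))
    expect_equal(sms, c(sm[-(seq_len(shift))], sm[seq_len(shift)]))
  }
  expect_error(rollingMeanCircular(zTrack(rnorm(10)), 500), "exceeds")
})

test_that("interval overlap fraction handles identity, disjoint, partial, wrap", {
  L <- 1000
  a <- GenomeFeatures(0, 100, L)
  expect_equal(intervalOverlapFraction(a, a)$symmetric, 1.0)
  b <- GenomeFeatures(500, 700, L)
  expect_equal(intervalOverlapFraction(a, b)$symmetric, 0.0)
  b2 <- GenomeFeatures(50, 150, L)
  r <- intervalOverlapFraction(a, b2)
  expect_equal(r$symmetric, 0.5)
  expect_equal(r$fracAinB, 0.5)
  # wrapping interval: [900, 50) covers 150 bp across the origin
  w <- GenomeFeatures(900, 50, L)
  expect_equal(sum(featureMask(w)), 150)
  r2 <- intervalOverlapFraction(w, a)
  expect_equal(r2$fracBinA, 0.5)  # 50 of a's 100 bp covered
  empty <- GenomeFeatures(genomeLength = L)
  r3 <- intervalOverlapFraction(empty, a)
  expect_equal(r3$fracAinB, 0)
  expect_true(isTRUE(attr(r3, "empty")))
})

test_that("rotation permutations preserve geometry and give valid p-values", {
  L <- 5000
  fs <- GenomeFeatures(c(10, 700, 4900), c(200, 1000, 150), L,
                       name = c("a", "b", "c"))
  rot <- rotateFeatures(fs, 300)
  expect_equal(length(rot), 3)
  expect_equal(sort(featureLengths(rot)), sort(featureLengths(fs)))
  expect_equal(rotateFeatures(fs, 0)@start, fs@start)
  # a constant statistic gives p = 1 under the add-one estimator
  r <- rotationPermutationTest(fs, function(f) 1.0, nPerm = 19, seed = 3)
  expect_equal(r$p, 1.0)
  # whole-genome feature: statistic invariant under rotation
  whole <- GenomeFeatures(0, L, L)
  covFrac <- function(f) mean(featureMask(f, L))
  r2 <- rotationPermutationTest(whole, covFrac, nPerm = 19, seed = 3)
  expect_equal(r2$p, 1.0)
  expect_true(all(r2$permuted == r2$observed))
  # reproducible under the seed
  r3 <- rotationPermutationTest(fs, covFrac, nPerm = 10, seed = 11)
  r4 <- rotationPermutationTest(fs, covFrac, nPerm = 10, seed = 11)
  expect_identical(r3, r4)
  expect_error(rotationPermutationTest(fs, function(f) NaN, 5, 1), "not finite")
})

test_that("mergeFeatures joins overlapping and bookended intervals, per name", {
  L <- 1000
  fs <- GenomeFeatures(c(0, 50, 100, 300), c(60, 100, 150, 400), L,
                       name = c("x", "x", "x", "x"), score = c(1, 5, 2, 3))
  m <- mergeFeatures(fs)
  expect_equal(length(m), 2)
  expect_equal(m@start, c(0, 300))
  expect_equal(m@end, c(150, 400))
  expect_equal(m@score[1], 5)  # max over merged members
  # name-aware merging keeps different TFs separate
  fs2 <- GenomeFeatures(c(0, 50), c(60, 100), L, name = c("tfA", "tfB"))
  expect_equal(length(mergeFeatures(fs2, byName = TRUE)), 2)
  # wrap-aware: [900, 1000) + [0, 50) are bookended across the origin
  fs3 <- GenomeFeatures(c(0, 900), c(50, 1000), L, name = "w")
  m3 <- mergeFeatures(fs3)
  expect_equal(length(m3), 1)
  expect_equal(sum(featureMask(m3)), 150)
})

test_that("binsForInterval maps bp intervals to bins, wrapping included", {
  tr <- zTrack(rnorm(20))  # 100 bp, res 5
  expect_equal(binsForInterval(0, 10, tr), 1:2)
  expect_equal(binsForInterval(7, 8, tr), 2L)
  expect_equal(binsForInterval(95, 5, tr), c(20L, 1L))
})
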