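test_that("a flat track yields no peaks at any threshold", {
  z <- zTrack(rep(0, 5000))
  pk <- callPeaksCwt(z)
  expect_equal(nrow(pk), 0)
})

test_that("a planted bump is called exactly once with correct localization", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 20000
    v <- plantGaussian(rnorm(n), centerBin = 10000, sdBins = 6, amplitude = 10)
    pk <- callPeaksCwt(zTrack(v))
    at4 <- pk[pk$snr >= 4, , drop = FALSE]
    apexOk <- nrow(at4) == 1 &&
      at4$start < 10000 * 5 && at4$end > 10000 * 5  # padded interval holds apex
    if (apexOk) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of seeds
})

test_that("padding arithmetic is exact and raw intervals sit inside padded", {
  set.seed(1)
  v <- plantGaussian(rnorm(8000), 4000, 8, 12)
  pk <- callPeaksCwt(zTrack(v), padBp = 30)
  expect_true(nrow(pk) >= 1)
  expect_equal(pk$start, pk$rawStart - 30)
  expect_equal(pk$end, pk$rawEnd + 30)
  expect_true(all(pk$rawEnd - pk$rawStart == pk$widthBp))
})

test_that("peak sets are nested across thresholds", {
  set.seed(12)
  v <- rnorm(20000)
  for (c0 in c(3000, 9000, 15000)) v <- plantGaussian(v, c0, 10, runif(1, 5, 12))
  pk <- callPeaksCwt(zTrack(v))
  L <- 20000 * 5
  prevApex <- NULL
  for (t in c(10, 8, 6, 4, 3, 2)) {
    at <- pk[pk$snr >= t, , drop = FALSE]
    if (!is.null(prevApex)) expect_true(all(prevApex %in% at$apexBp))
    prevApex <- at$apexBp
  }
  # the threshold label is the most stringent passed threshold
  expect_true(all(pk$minSnrThreshold <= pk$snr))
  expect_true(all(pk$snr < vapply(pk$minSnrThreshold, function(t) {
    nxt <- c(2, 3, 4, 6, 8, 10)[c(2, 3, 4, 6, 8, 10) > t]
    if (length(nxt)) min(nxt) else Inf
  }, numeric(1))))
})

test_that("planted peaks are recovered with high recall and precision", {
  nSeeds <- 20
  rec <- prec <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    set.seed(100 + s)
    n <- 20000; L <- n * 5
    centers <- seq(1000, 19000, length.out = 12) + sample(-200:200, 12, TRUE)
    widths <- sample(seq(50, 150, 10), 12, TRUE)
    v <- rnorm(n)
    for (i in seq_len(12))
      v <- plantGaussian(v, centers[i], widths[i] / 5 / 2, runif(1, 8, 12))
    pk <- peaksAtThreshold(callPeaksCwt(zTrack(v)), 4, L)
    called <- peaksToFeatures(pk, L)
    tr <- GenomeFeatures((centers - widths / 5) * 5, (centers + widths / 5) * 5, L)
    hitT <- vapply(seq_len(12), function(i) {
      any(pk$apexBp >= tr@start[i] & pk$apexBp <= tr@end[i])
    }, logical(1))
    hitC <- vapply(seq_len(nrow(pk)), function(j) {
      any(pk$apexBp[j] >= tr@start & pk$apexBp[j] <= tr@end)
    }, logical(1))
    rec[s] <- mean(hitT); prec[s] <- mean(hitC)
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
})

test_that("scoring floors at the mean and flags negative-mean peaks", {
  z <- zTrack(c(rep(0, 20), rep(4.7, 10), rep(0, 20)))
  pk <- data.frame(apexBp = 125, widthBp = 50, snr = 10, minSnrThreshold = 4,
                   rawStart = 100, rawEnd = 150, start = 70, end = 180)
  sc <- scorePeaks(pk, z)
  expect_equal(sc$meanZ, 4.7)
  expect_equal(sc$discreteScore, 4)
  z2 <- zTrack(c(rep(0, 20), rep(4.0, 10), rep(0, 20)))
  expect_equal(scorePeaks(pk, z2)$discreteScore, 4)
  zneg <- zTrack(rep(-1, 50))
  expect_warning(scorePeaks(pk, zneg), "negative")
})

test_that("overlapping padded peaks merge and keep the minimum label", {
  pk <- data.frame(apexBp = c(500, 560), widthBp = c(50, 50), snr = c(9, 5),
                   minSnrThreshold = c(8, 4), rawStart = c(475, 535),
                   rawEnd = c(525, 585), start = c(445, 505), end = c(555, 615))
  m <- peaksAtThreshold(pk, 4, 10000)
  expect_equal(nrow(m), 1)
  expect_equal(m$minSnrThreshold, 4)
  expect_equal(m$snr, 9)
  expect_equal(m$start, 445)
  expect_equal(m$end, 615)
  # at threshold 8 only the stronger peak remains, unmerged
  m8 <- peaksAtThreshold(pk, 8, 10000)
  expect_equal(nrow(m8), 1)
  expect_equal(m8$end, 555)
})

test_that("site enrichment under peaks behaves at the boundary cases", {
  L <- 50000
  whole <- GenomeFeatures(0, L, L)
  sites <- GenomeFeatures(seq(0, 45000, by = 5000), seq(0, 45000, by = 5000) + 50, L)
  r <- peakSiteOverlap(whole, sites, L, nPerm = 20, seed = 1)
  expect_equal(r$enrichment, 1.0)
  expect_equal(r$p, 1.0)
  # sparse peaks identical to sites -> enrichment over the chance rate
  peaks <- sites
  r2 <- peakSiteOverlap(peaks, sites, L, nPerm = 50, seed = 2)
  expect_gt(r2$enrichment, 1)
  expect_lt(r2$p, 0.05)
})
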