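.ratioTracks <- function(ratios, chipTop = 100, nPad = 2000) {
  # build aligned tracks where the top-|ratios| ChIP bins have the given
  # ipod/chip ratios and the rest sit well below the top-2% cutoff
  n <- length(ratios)
  stopifnot(ceiling(0.02 * (n + nPad)) == n)
  chip <- c(rep(chipTop, n), seq(0.1, 1, length.out = nPad))
  ipod <- c(ratios * chipTop, seq(-1, 1, length.out = nPad))
  list(ipod = zTrack(ipod), chip = zTrack(chip))
}

test_that("the subtraction slope is the stated order statistic", {
  # proportional data: ipod = 2 x chip on the selected bins
  tt <- .ratioTracks(rep(2, 41), nPad = 2009)
  m <- fitSubtractionSlope(tt$ipod, tt$chip)
  expect_equal(m@slope, 2)
  # ratios 1..20 among top bins is the textbook case: cover 0.95 -> 19
  tt2 <- .ratioTracks(1:20, nPad = 980)  # 20 = ceil(0.02 * 1000)
  m2 <- fitSubtractionSlope(tt2$ipod, tt2$chip)
  expect_equal(m2@slope, 19)
  # all-negative ratios clamp to zero
  tt3 <- .ratioTracks(-(1:20), nPad = 980)
  m3 <- fitSubtractionSlope(tt3$ipod, tt3$chip)
  expect_equal(m3@slope, 0)
  expect_error(fitSubtractionSlope(zTrack(rnorm(100)), zTrack(rep(-1, 100))),
               "positive-ChIP")
})

test_that("fitted slope equals the brute-force minimal slope on random sets", {
  set.seed(8)
  for (i in 1:10) {
    ratios <- round(runif(20, 0, 5), 3)
    tt <- .ratioTracks(ratios, nPad = 980)
    m <- fitSubtractionSlope(tt$ipod, tt$chip)
    expect_equal(m@slope, bruteForceSlope(ratios, 0.95), tolerance = 2e-4)
  }
})

test_that("subtraction only lowers occupancy and skips negative ChIP", {
  model <- new("ChipSubModel", slope = 1.5, topFrac = 0.02, coverFrac = 0.95,
               nFitPoints = 20L)
  ipod <- zTrack(c(5, 5, 3)); chip <- zTrack(c(2, -0.5, 0))
  out <- binValues(subtractRnap(ipod, chip, model))
  expect_equal(out, c(5 - 1.5 * 2, 5, 3))  # no subtraction at chip <= 0
  set.seed(9)
  ip <- zTrack(rnorm(500)); ch <- zTrack(rnorm(500))
  expect_true(all(binValues(subtractRnap(ip, ch, model)) <= binValues(ip) + 1e-12))
})

test_that("robust z uses the unscaled MAD and is affine-equivariant", {
  tr <- zTrack(c(1, 2, 3, 4, 5))
  expect_equal(binValues(robustZ(tr)), c(-2, -1, 0, 1, 2))
  set.seed(10)
  x <- rnorm(200)
  z <- binValues(robustZ(zTrack(x)))
  expect_equal(median(z), 0)
  expect_equal(mad(z, constant = 1), 1)
  # affine invariance: robustZ(a x + b) = sign(a) robustZ(x)
  za <- binValues(robustZ(zTrack(-3 * x + 7)))
  expect_equal(za, -z, tolerance = 1e-12)
  expect_error(robustZ(zTrack(rep(1, 10))), "MAD")
})

test_that("tail p-values match the standard normal and stay precise", {
  expect_equal(neglog10Pvalues(0), -log10(0.5), tolerance = 1e-9)
  expect_equal(neglog10Pvalues(3), 2.8697, tolerance = 1e-4)
  # large z: the direct tail underflows but the log path stays finite
  expect_true(is.finite(neglog10Pvalues(50)))
  expect_equal(neglog10Pvalues(50), -pnorm(50, lower.tail = FALSE, log.p = TRUE) / log(10))
  zs <- seq(-4, 8, by = 0.25)
  expect_true(all(diff(neglog10Pvalues(zs)) > 0))
})

test_that("replicate-extreme intervals match explicit enumeration", {
  truth <- randomSyntheticTruth(genomeLength = 5e4, seed = 41, nTf = 5,
                                nRnap = 5, nEpod = 1)
  bundle <- normalizeCondition(generateCondition(truth, seed = 42,
                                                 nReplicates = c(input = 2, ipod = 2, chip = 2)))
  li <- replicateExtremeInterval(bundle)
  # brute-force enumeration of the 8 combinations
  mats <- list()
  for (i in 1:2) for (cc in 1:2) for (nn in 1:2) {
    ip <- log2Ratio(bundle@ipod[[i]], bundle@input[[nn]])
    ch <- log2Ratio(bundle@chip[[cc]], bundle@input[[nn]])
    mod <- fitSubtractionSlope(ip, ch)
    mats[[length(mats) + 1]] <- binValues(neglog10Pvalues(robustZ(subtractRnap(ip, ch, mod))))
  }
  mm <- do.call(cbind, mats)
  expect_equal(binValues(li$lo), apply(mm, 1, min))
  expect_equal(binValues(li$hi), apply(mm, 1, max))
  expect_true(all(binValues(li$lo) <= binValues(li$hi)))
  # single replicate per type: lo = hi = point estimate
  b1 <- ConditionBundle(bundle@input[1], bundle@ipod[1], bundle@chip[1])
  li1 <- replicateExtremeInterval(b1)
  expect_equal(binValues(li1$lo), binValues(li1$hi))
  expect_error(replicateExtremeInterval(bundle, cap = 4), "cap")
})

test_that("after subtraction the top-ChIP bins are covered as designed", {
  truth <- randomSyntheticTruth(genomeLength = 1e5, seed = 51, nTf = 0,
                                nEpod = 0, nRnap = 15)
  bundle <- normalizeCondition(generateCondition(truth, seed = 52))
  prof <- scoreCondition(bundle)
  ch <- binValues(bundle@derived$chipLog2)
  cs <- binValues(prof@chipsub)
  top <- order(ch, decreasing = TRUE)[seq_len(ceiling(0.02 * length(ch)))]
  expect_gte(mean(cs[top] <= 1e-9), 0.95)
})
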