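test_that("quantile normalization equalizes distributions", {
  a <- zTrack(c(1, 2, 3)); b <- zTrack(c(2, 4, 6))
  out <- quantileNormalize(list(a, b))
  expect_equal(binValues(out[[1]]), c(1.5, 3, 4.5))
  expect_equal(binValues(out[[2]]), c(1.5, 3, 4.5))
  # identical tracks unchanged; single track returned as is
  out2 <- quantileNormalize(list(a, a))
  expect_equal(binValues(out2[[1]]), c(1, 2, 3))
  expect_equal(length(quantileNormalize(list(a))), 1)
  # sorted value vectors identical across outputs on random tracks
  set.seed(2)
  trs <- lapply(1:3, function(i) zTrack(rlnorm(200)))
  qn <- quantileNormalize(trs)
  srt <- lapply(qn, function(t) sort(binValues(t)))
  expect_equal(srt[[1]], srt[[2]])
  expect_equal(srt[[2]], srt[[3]])
  expect_error(quantileNormalize(list(a, zTrack(rnorm(5)))), "aligned")
})

test_that("the periodic spline recovers smooth gradients", {
  # constant track -> constant spline
  ct <- zTrack(rep(3, 2000))
  sp <- fitPeriodicSpline(ct)
  expect_equal(binValues(sp), rep(3, 2000), tolerance = 1e-6)
  # 2 + cos track recovered with RMSE < 1% of amplitude
  n <- 2000; L <- n * 5
  x <- (seq_len(n) - 0.5) * 5
  y <- 2 + cos(2 * pi * x / L)
  sp2 <- fitPeriodicSpline(zTrack(y))
  expect_lt(sqrt(mean((binValues(sp2) - y)^2)), 0.01)
  # equivariance: refit on a quarter-turn rotation equals rotated fit
  shift <- n / 4
  yr <- c(y[-(seq_len(shift))], y[seq_len(shift)])
  spr <- fitPeriodicSpline(zTrack(yr))
  expected <- c(binValues(sp2)[-(seq_len(shift))], binValues(sp2)[seq_len(shift)])
  expect_equal(binValues(spr), expected, tolerance = 1e-3)
})

test_that("copy-number correction flattens the gradient it models", {
  n <- 2000; L <- n * 5
  x <- (seq_len(n) - 0.5) * 5
  grad <- exp(0.35 * cos(2 * pi * x / L))
  mk <- function() GenomeTrack(grad, L, 5)
  bundle <- ConditionBundle(mk(), mk(), mk())
  cc <- copyNumberCorrect(bundle)
  expect_equal(binValues(cc@input[[1]]), rep(1, n), tolerance = 0.01)
  # doubling the gradient amplitude leaves corrected tracks unchanged
  grad2 <- grad^2  # gradient_fold squared
  b2 <- ConditionBundle(GenomeTrack(grad2, L, 5), GenomeTrack(grad2, L, 5),
                        GenomeTrack(grad2, L, 5))
  cc2 <- copyNumberCorrect(b2)
  expect_equal(binValues(cc2@ipod[[1]]), binValues(cc@ipod[[1]]), tolerance = 0.02)
  # flat tracks unchanged (constant spline)
  bf <- ConditionBundle(zTrack(rep(2, 500)), zTrack(rep(2, 500)), zTrack(rep(2, 500)))
  ccf <- copyNumberCorrect(bf)
  expect_equal(binValues(ccf@chip[[1]]), rep(1, 500), tolerance = 1e-6)
})

test_that("mean matching and replicate averaging behave arithmetically", {
  a <- zTrack(rep(1, 10)); b <- zTrack(rep(3, 10))
  mm <- matchMeans(list(a, b))
  expect_equal(mean(binValues(mm[[1]])), 2)
  expect_equal(mean(binValues(mm[[2]])), 2)
  expect_equal(binValues(matchMeans(list(b))[[1]]), rep(3, 10))
  set.seed(3)
  trs <- lapply(1:3, function(i) zTrack(rlnorm(100)))
  mm2 <- matchMeans(trs)
  mns <- vapply(mm2, function(t) mean(binValues(t)), numeric(1))
  expect_equal(max(mns) - min(mns), 0, tolerance = 1e-9 * mns[1])
  expect_error(matchMeans(list(zTrack(rep(-1, 5)))), "positive")
  # averaging
  expect_equal(binValues(averageReplicates(list(a, a))), rep(1, 10))
  expect_equal(binValues(averageReplicates(list(zTrack(c(0, 2)), zTrack(c(2, 0))))),
               c(1, 1))
  x1 <- rnorm(50); x2 <- rnorm(50)
  avg <- averageReplicates(list(zTrack(x1), zTrack(x2)))
  expect_equal(mean(binValues(avg)), mean(c(mean(x1), mean(x2))))
})

test_that("log2 ratios are zero at equality and antisymmetric", {
  set.seed(4)
  a <- zTrack(rlnorm(100)); b <- zTrack(rlnorm(100))
  expect_equal(binValues(log2Ratio(a, a)), rep(0, 100))
  quad <- a; quad@values <- 4 * a@values
  expect_equal(binValues(log2Ratio(quad, a)), rep(2, 100))
  expect_equal(binValues(log2Ratio(a, b)), -binValues(log2Ratio(b, a)))
  # missing input propagates
  bm <- b; bm@values[3] <- NA
  expect_true(is.na(binValues(log2Ratio(a, bm))[3]))
})

test_that("the chain is idempotent and flattens a pure gradient condition", {
  truth <- syntheticTruth(genomeLength = 1e5)  # gradient + noise, no features
  bundle <- normalizeCondition(generateCondition(truth, seed = 31))
  v <- binValues(bundle@derived$ipodLog2)
  expect_gte(mean(abs(v) < 0.05), 0.99)
  # quantile + mean-match applied twice equals once (to tolerance)
  once <- matchMeans(quantileNormalize(bundle@input))
  twice <- matchMeans(quantileNormalize(once))
  expect_equal(binValues(twice[[1]]), binValues(once[[1]]), tolerance = 1e-8)
})
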