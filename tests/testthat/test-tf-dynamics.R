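.toyProfile <- function(pvals, zvals = NULL, res = 5) {
  n <- length(pvals)
  if (is.null(zvals)) zvals <- pvals
  new("ScoredProfile", condition = "toy",
      chipsub = zTrack(pvals, res), robustZ = zTrack(zvals, res),
      neglog10p = zTrack(pvals, res), replicateLo = NULL, replicateHi = NULL,
      model = NULL)
}

test_that("site occupancy is the within-site maximum and merges per TF", {
  p <- c(0.2, 4.1, 1.0, 0.1, 0.3, 2.2, 0.2, 0.1)
  z <- c(0.1, 5.0, 1.0, 0.0, 0.2, 2.0, 0.1, 0.0)
  prof <- .toyProfile(p, z)
  sites <- GenomeFeatures(c(0, 25), c(15, 30), 40, name = c("tfA", "tfB"))
  tab <- siteOccupancy(prof, sites)
  expect_equal(tab$occupancy[tab$tf == "tfA"], 4.1)
  expect_equal(tab$occupancy[tab$tf == "tfB"], 2.2)
  expect_true(tab$detectable[tab$tf == "tfA"])   # max z 5 > 3
  expect_false(tab$detectable[tab$tf == "tfB"])  # max z 2
  # single-bin site
  s1 <- GenomeFeatures(10, 15, 40, name = "tfC")
  expect_equal(siteOccupancy(prof, s1)$occupancy, 1.0)
  # overlapping same-TF sites are merged before analysis
  sov <- GenomeFeatures(c(0, 10), c(15, 30), 40, name = "tfA")
  expect_equal(nrow(siteOccupancy(prof, sov)), 1)
})

test_that("TF scores are floored geometric means with unit row maxima", {
  mkTab <- function(occ, z = 10) {
    data.frame(tf = rep("tf1", length(occ)), start = seq_along(occ) * 100,
               end = seq_along(occ) * 100 + 20, occupancy = occ,
               maxZ = z, detectable = z > 3)
  }
  m <- tfConditionScore(list(c1 = mkTab(c(1, 4)), c2 = mkTab(c(2, 2))))
  expect_equal(unname(m@scores["tf1", "c1"]), 2.0)  # sqrt(1 x 4)
  expect_equal(unname(m@scores["tf1", "c2"]), 2.0)
  # floor at 0.01: geometric mean of (0.001 -> 0.01, 100) = 1
  m2 <- tfConditionScore(list(c1 = mkTab(c(0.001, 100))))
  expect_equal(unname(m2@scores["tf1", "c1"]), 1.0)
  # normalized rows peak at exactly 1
  tabs <- list(a = mkTab(c(1, 2, 3)), b = mkTab(c(4, 5, 6)), c = mkTab(c(2, 2, 2)))
  m3 <- tfConditionScore(tabs)
  expect_equal(max(m3@normalized["tf1", ]), 1.0)
  # geometric mean bounded by floored min/max of the sites
  occ <- c(0.5, 7, 2)
  g <- unname(tfConditionScore(list(x = mkTab(occ)))@scores[1, 1])
  expect_gte(g, 0.5)
  expect_lte(g, 7)
  # undetectable sites are excluded
  und <- mkTab(c(5, 5), z = 1)
  expect_error(tfConditionScore(list(c1 = und)), "detectable")
})

test_that("bootstrap CIs are seeded, degenerate-safe, and cover the estimate", {
  occ <- c(2, 3, 4)
  # zero replicate range -> zero-width CI at the point estimate
  ci0 <- bootstrapSiteCi(occ, lo = occ, hi = occ, nBoot = 100, seed = 1)
  expect_equal(unname(ci0["lo"]), unname(ci0["hi"]))
  expect_equal(unname(ci0["lo"]), unname(ci0["estimate"]))
  # same seed -> identical CI; different seed -> (generically) different
  lo <- occ - 0.5; hi <- occ + 0.7
  a <- bootstrapSiteCi(occ, lo, hi, nBoot = 200, seed = 7)
  b <- bootstrapSiteCi(occ, lo, hi, nBoot = 200, seed = 7)
  expect_identical(a, b)
  # point estimate within the CI across synthetic cases
  set.seed(8)
  inside <- vapply(1:200, function(i) {
    m <- runif(5, 0.5, 5)
    rng <- m * runif(5, 0.05, 0.5)
    ci <- bootstrapSiteCi(m, m - rng / 2, m + rng / 2, nBoot = 300, seed = i)
    ci["lo"] <= ci["estimate"] && ci["estimate"] <= ci["hi"]
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("consensus clustering recovers planted structure", {
  # identical rows always co-cluster
  mat <- rbind(a = c(1, 0, 0), a2 = c(1, 0, 0), b = c(0, 1, 0), b2 = c(0, 1, 0),
               c = c(0, 0, 1), d = c(0.5, 0.5, 0), e = c(0, 0.5, 0.5),
               f = c(0.5, 0, 0.5), g = c(1, 1, 0), h = c(0, 1, 1),
               i = c(1, 0, 1), j = c(0.2, 0.2, 0.6))
  cc <- consensusCluster(mat, nRuns = 20, kRange = 4:6, nFinal = 10, seed = 1)
  expect_equal(cc@kappa["a", "a2"], 1.0)
  expect_equal(cc@kappa["b", "b2"], 1.0)
  expect_true(isSymmetric(cc@kappa))
  expect_equal(unname(diag(cc@kappa)), rep(1, 12))
  # reproducible bit for bit under the master seed
  cc2 <- consensusCluster(mat, nRuns = 20, kRange = 4:6, nFinal = 10, seed = 1)
  expect_identical(cc@kappa, cc2@kappa)
  expect_identical(cc@labels, cc2@labels)
  # 10 planted groups recovered exactly
  pl <- plantedTfMatrix(seed = 2)
  cc3 <- consensusCluster(pl$mat, nRuns = 100, kRange = 8:12, nFinal = 10, seed = 3)
  expect_true(samePartition(cc3@labels, pl$groups))
})

test_that("regulon Jaccard indices follow the set definition", {
  expect_equal(jaccardRegulons(c("x", "y"), c("x", "y")), 1.0)
  expect_equal(jaccardRegulons(c("x"), c("y")), 0.0)
  expect_equal(jaccardRegulons(c("a", "b"), c("b", "c")), 1 / 3)
  r <- jaccardRegulons(character(), character())
  expect_equal(as.numeric(r), 0)
  expect_true(isTRUE(attr(r, "empty")))
})
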