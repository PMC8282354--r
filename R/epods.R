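#' Parameters for EPOD calling
#'
#' @param kPercentile Percentile of the 256-bp rolling mean defining the
#'   occupancy threshold: 90 for strict calls, 75 for the relaxed set.
#' @param seedWindowBp Rolling-mean window used to find seeds (512 bp).
#' @param thresholdWindowBp Rolling-mean window defining the threshold
#'   distribution (256 bp).
#' @param minSeedBp Minimum seed length (1024 bp).
#' @param floorZ Extension may not cross a bin with robust z at or below this
#'   floor (0).
#' @return A named list of parameters.
#' @export
epodParams <- function(kPercentile = 90, seedWindowBp = 512,
                       thresholdWindowBp = 256, minSeedBp = 1024,
                       floorZ = 0) {
  stopifnot(kPercentile > 0, kPercentile < 100, minSeedBp >= seedWindowBp)
  list(kPercentile = kPercentile, seedWindowBp = seedWindowBp,
       thresholdWindowBp = thresholdWindowBp, minSeedBp = minSeedBp,
       floorZ = floorZ)
}

# Maximal circular runs of TRUE; returns matrix with 1-based first/last bin
# columns (last may be < first for a wrap) and run length.
.circularRuns <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(NULL)
  if (all(flag)) return(cbind(first = 1, last = n, len = n))
  rot <- which(!flag)[1]  # rotate so the vector starts with FALSE
  f2 <- flag[c(rot:n, seq_len(rot - 1))]
  r <- rle(f2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  first <- (starts[keep] + rot - 2) %% n + 1
  last <- (ends[keep] + rot - 2) %% n + 1
  cbind(first = first, last = last, len = r$lengths[keep])
}

#' Call extended protein occupancy domains (EPODs)
#'
#' Seed-and-extend detection of kilobase-scale dense occupancy on the robust-z
#' track. The threshold `T` is the `kPercentile`-th percentile (linear
#' interpolation) of the 256-bp rolling mean over the whole chromosome. Seeds
#' are maximal regions of at least 1,024 bp over which the 512-bp rolling mean
#' exceeds `T`; among overlapping seeds only the highest-mean one is kept
#' (applied iteratively). Each seed is then extended greedily bin by bin in
#' both directions -- at each step the side with the larger next value is
#' tried first (ties go left) -- for as long as the mean over the whole call
#' stays above `T` and the next bin's z exceeds `floorZ` (missing bins
#' block). Extension never enters bins claimed by a previously emitted
#' (higher-mean) call, and calls that come to abut are reported separately.
#'
#' @param z Robust-z [GenomeTrack-class].
#' @param params From [epodParams()]; `kPercentile = 90` gives the strict
#'   set, 75 the relaxed set.
#' @return A [GenomeFeatures-class] of EPOD intervals, scores = mean robust z
#'   over the call, source = `"epod_k<k>"`. Attribute `"threshold"` carries
#'   `T`.
#' @export
callEpods <- function(z, params = epodParams()) {
  if (all(is.na(z@values))) stop("track is all-missing")
  res <- z@resolution
  n <- nBins(z)
  rThr <- rollingMeanCircular(z, params$thresholdWindowBp)@values
  Tthr <- stats::quantile(rThr, params$kPercentile / 100, na.rm = TRUE,
                          names = FALSE, type = 7)
  rSeed <- rollingMeanCircular(z, params$seedWindowBp)@values
  above <- !is.na(rSeed) & rSeed > Tthr
  runs <- .circularRuns(above)
  empty <- GenomeFeatures(genomeLength = z@genomeLength, chrom = z@chrom)
  attr(empty, "threshold") <- Tthr
  if (is.null(runs)) return(empty)
  minBins <- ceiling(params$minSeedBp / res)
  runs <- runs[runs[, "len"] >= minBins, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  zv <- z@values
  runBins <- function(first, last) {
    if (last >= first) first:last else c(first:n, 1:last)
  }
  seedMean <- apply(runs, 1, function(r) mean(zv[runBins(r["first"], r["last"])], na.rm = TRUE))
  # overlapping seeds: keep the highest mean, iteratively (maximal runs are
  # disjoint by construction, so this is a faithfulness no-op in practice)
  ord <- order(seedMean, decreasing = TRUE)
  runs <- runs[ord, , drop = FALSE]; seedMean <- seedMean[ord]
  claimed <- logical(n)
  calls <- list()
  for (i in seq_len(nrow(runs))) {
    bins <- runBins(runs[i, "first"], runs[i, "last"])
    if (any(claimed[bins])) next
    lo <- runs[i, "first"]; hi <- runs[i, "last"]
    s <- sum(zv[bins], na.rm = TRUE); cnt <- length(bins)
    usable <- function(b) {
      cnt < n && !claimed[b] && !is.na(zv[b]) && zv[b] > params$floorZ
    }
    repeat {
      bl <- (lo - 2) %% n + 1  # bin before lo
      br <- hi %% n + 1        # bin after hi
      okL <- usable(bl); okR <- usable(br)
      if (!okL && !okR) break
      pickL <- okL && (!okR || zv[bl] >= zv[br])  # ties go left
      grew <- FALSE
      for (side in if (pickL) c("L", "R") else c("R", "L")) {
        if (side == "L" && okL && (s + zv[bl]) / (cnt + 1) > Tthr) {
          lo <- bl; s <- s + zv[bl]; cnt <- cnt + 1; grew <- TRUE; break
        }
        if (side == "R" && okR && (s + zv[br]) / (cnt + 1) > Tthr) {
          hi <- br; s <- s + zv[br]; cnt <- cnt + 1; grew <- TRUE; break
        }
      }
      if (!grew) break
    }
    bins <- runBins(lo, hi)
    claimed[bins] <- TRUE
    startBp <- (lo - 1) * res
    endBp <- min(hi * res, z@genomeLength)
    calls[[length(calls) + 1L]] <-
      data.frame(start = startBp, end = endBp, meanZ = s / cnt)
  }
  if (length(calls) == 0) return(empty)
  df <- do.call(rbind, calls)
  out <- GenomeFeatures(df$start, df$end, z@genomeLength, score = df$meanZ,
                        name = sprintf("epod_%d", seq_len(nrow(df))),
                        source = sprintf("epod_k%g", params$kPercentile),
                        chrom = z@chrom)
  attr(out, "threshold") <- Tthr
  out
}

#' Pairwise symmetrized EPOD overlap between conditions
#'
#' Entry (a, b) is the average of the fraction of EPOD base pairs of
#' condition `a` also called in condition `b` and vice versa.
#'
#' @param epodSets Named list of [GenomeFeatures-class] EPOD sets.
#' @param genomeLength Genome length in bp.
#' @return Symmetric matrix with unit diagonal.
#' @export
epodOverlapMatrix <- function(epodSets, genomeLength = NULL) {
  stopifnot(length(epodSets) >= 2)
  L <- if (is.null(genomeLength)) epodSets[[1]]@genomeLength else genomeLength
  k <- length(epodSets)
  m <- diag(1, k)
  dimnames(m) <- list(names(epodSets), names(epodSets))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <-
      intervalOverlapFraction(epodSets[[i]], epodSets[[j]], L)$symmetric
  }
  m
}

#' Fraction of strict EPOD base pairs contained in a relaxed set
#'
#' @param strictA Strict EPOD calls of one sample.
#' @param relaxedB Relaxed (k = 75) EPOD calls of another sample.
#' @param genomeLength Genome length in bp.
#' @return Fraction in [0, 1]; 0 (flagged by attribute `"empty"`) when the
#'   strict set is empty.
#' @export
epodContainment <- function(strictA, relaxedB, genomeLength = NULL) {
  L <- if (is.null(genomeLength)) strictA@genomeLength else genomeLength
  ma <- featureMask(strictA, L)
  if (!any(ma)) { out <- 0; attr(out, "empty") <- TRUE; return(out) }
  mb <- featureMask(relaxedB, L)
  sum(ma & mb) / sum(ma)
}

#' Enrichment of a genomic feature track inside EPODs
#'
#' The feature track is smoothed with a 500-bp rolling mean, then the
#' difference of medians (inside EPODs minus outside) is tested against a
#' null of random circular rotations of the EPOD locations, which preserves
#' the correlation structure of both the track and the domain set.
#'
#' @param epods EPOD [GenomeFeatures-class].
#' @param featureTrack Aligned [GenomeTrack-class] of the genomic feature.
#' @param nPerm Number of rotations (default 1000).
#' @param seed Integer seed.
#' @param smoothBp Pre-smoothing window (default 500 bp).
#' @return List with `medianDiff`, `p`, and the permutation distribution.
#' @export
epodFeatureEnrichment <- function(epods, featureTrack, nPerm = 1000, seed = 1,
                                  smoothBp = 500) {
  sm <- rollingMeanCircular(featureTrack, smoothBp)@values
  n <- length(sm)
  trk <- featureTrack
  statistic <- function(fs) {
    inside <- logical(n)
    for (i in seq_along(fs@start))
      inside[binsForInterval(fs@start[i], fs@end[i], trk)] <- TRUE
    stats::median(sm[inside], na.rm = TRUE) -
      stats::median(sm[!inside], na.rm = TRUE)
  }
  rt <- rotationPermutationTest(epods, statistic, nPerm, seed)
  list(medianDiff = rt$observed, p = rt$p, permuted = rt$permuted)
}
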