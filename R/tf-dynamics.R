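#' Site-level occupancy summary for annotated binding sites
#'
#' Overlapping or bookended sites of the same transcription factor are merged
#' before analysis. For each merged site the occupancy is the maximum -log10
#' p over the site's bins (the peak of the binding signal) and the site is
#' flagged detectable when its maximum robust z exceeds `detectZ`.
#'
#' @param profile A [ScoredProfile-class].
#' @param sites A [GenomeFeatures-class] of binding sites with `name` = TF.
#' @param detectZ Detectability threshold on the per-site maximum robust z
#'   (default 3).
#' @return A data.frame with columns `tf`, `start`, `end`, `occupancy`,
#'   `maxZ`, `detectable`, plus pessimistic bounds `lo`/`hi` when the profile
#'   carries a replicate-extreme interval. Sites with no usable bins are
#'   dropped with a message.
#' @export
siteOccupancy <- function(profile, sites, detectZ = 3) {
  merged <- mergeFeatures(sites, byName = TRUE, bookended = TRUE)
  p <- profile@neglog10p; z <- profile@robustZ
  hasRep <- !is.null(profile@replicateLo)
  n <- length(merged)
  occ <- maxz <- lo <- hi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    bins <- binsForInterval(merged@start[i], merged@end[i], p)
    pv <- p@values[bins]
    if (all(is.na(pv))) next
    occ[i] <- max(pv, na.rm = TRUE)
    maxz[i] <- max(z@values[bins], na.rm = TRUE)
    if (hasRep) {
      lo[i] <- max(profile@replicateLo@values[bins], na.rm = TRUE)
      hi[i] <- max(profile@replicateHi@values[bins], na.rm = TRUE)
    }
  }
  out <- data.frame(tf = merged@name, start = merged@start, end = merged@end,
                    occupancy = occ, maxZ = maxz, detectable = maxz > detectZ)
  if (hasRep) { out$lo <- lo; out$hi <- hi }
  drop <- is.na(out$occupancy)
  if (any(drop)) {
    message(sum(drop), " site(s) with no usable signal dropped")
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.geomMean <- function(x, floor) exp(mean(log(pmax(x, floor))))

#' TF-by-condition occupancy score matrix
#'
#' Each TF's score in a condition is the geometric mean of its site-level
#' occupancies (-log10 p, floored at `floor`); the normalized matrix divides
#' each TF row by its maximum across conditions, so the highest-occupancy
#' condition of every TF scores 1. Only sites detectable (max robust z above
#' the threshold) in at least one condition contribute, and TFs with fewer
#' than `minSites` such sites are dropped.
#'
#' @param siteTables Named list (one per condition) of data.frames from
#'   [siteOccupancy()], with identical site rows per condition.
#' @param floor Site-level floor (default 0.01).
#' @param minSites Minimum detectable sites per TF (default 1).
#' @return A [TFOccupancyMatrix-class].
#' @export
tfConditionScore <- function(siteTables, floor = 0.01, minSites = 1L) {
  stopifnot(length(siteTables) >= 1)
  conds <- names(siteTables)
  ref <- siteTables[[1]]
  det <- Reduce(`|`, lapply(siteTables, function(t) t$detectable))
  keep <- which(det)
  tfs <- sort(unique(ref$tf[keep]))
  counts <- table(ref$tf[keep])
  tfs <- tfs[counts[tfs] >= minSites]
  if (length(tfs) == 0) stop("no TF has enough detectable sites")
  scores <- matrix(NA_real_, length(tfs), length(siteTables),
                   dimnames = list(tfs, conds))
  for (j in seq_along(siteTables)) {
    tab <- siteTables[[j]]
    for (tf in tfs) {
      idx <- intersect(keep, which(tab$tf == tf))
      scores[tf, j] <- .geomMean(tab$occupancy[idx], floor)
    }
  }
  normalized <- scores / apply(scores, 1, max)
  new("TFOccupancyMatrix", scores = scores, normalized = normalized,
      nSites = stats::setNames(as.integer(counts[tfs]), tfs))
}

#' Parametric bootstrap confidence interval for a TF's average occupancy
#'
#' Pessimistic replicate-combination bounds give each site a range; the
#' site's occupancy is modeled as log-normal with arithmetic mean equal to
#' the observed value and arithmetic standard deviation equal to one quarter
#' of that range (so the range behaves like an approximate 95% interval).
#' Each bootstrap replicate resamples every site and recomputes the TF-level
#' geometric mean; the CI is the 2.5/97.5 percentile band over `nBoot`
#' replicates.
#'
#' @param occupancy Observed site occupancies (-log10 p).
#' @param lo,hi Pessimistic replicate-combination bounds per site.
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed Integer seed (deterministic output).
#' @param floor Site-level floor used in the geometric mean.
#' @param logScaleNormal If `TRUE`, use the documented alternative of a
#'   normal distribution on the log scale with matching log-mean/sd instead
#'   of arithmetic moment matching.
#' @return Named numeric vector `c(lo, hi, estimate)`.
#' @export
bootstrapSiteCi <- function(occupancy, lo, hi, nBoot = 1000, seed = 1,
                            floor = 0.01, logScaleNormal = FALSE) {
  stopifnot(length(lo) == length(occupancy), length(hi) == length(occupancy))
  m <- pmax(occupancy, floor)
  s <- (hi - lo) / 4
  draws <- withr::with_seed(seed, {
    vapply(seq_len(nBoot), function(b) {
      x <- vapply(seq_along(m), function(i) {
        if (s[i] <= 0) return(m[i])
        if (logScaleNormal) {
          stats::rlnorm(1, meanlog = log(m[i]), sdlog = s[i] / m[i])
        } else {
          sig2 <- log(1 + (s[i] / m[i])^2)
          stats::rlnorm(1, meanlog = log(m[i]) - sig2 / 2, sdlog = sqrt(sig2))
        }
      }, numeric(1))
      .geomMean(x, floor)
    }, numeric(1))
  })
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  c(lo = ci[1], hi = ci[2], estimate = .geomMean(m, floor))
}

# K-means with a seeded random start robust to duplicate rows: centers are
# sampled among distinct rows (jittered as a last resort).
.kmeansOnce <- function(mat, k) {
  uniq <- unique(mat)
  # K-means needs fewer centers than points and no more than the distinct
  # profiles
  k <- max(1L, min(k, nrow(uniq), nrow(mat) - 1L))
  for (attempt in seq_len(50)) {
    if (nrow(uniq) >= k) {
      centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
    } else {
      centers <- uniq[sample.int(nrow(uniq), k, replace = TRUE), , drop = FALSE]
      centers <- centers + matrix(stats::rnorm(length(centers), 0, 1e-9),
                                  nrow(centers))
    }
    fit <- tryCatch(stats::kmeans(mat, centers = centers, iter.max = 100),
                    error = function(e) NULL)
    if (!is.null(fit)) return(fit$cluster)
  }
  stop("K-means failed repeatedly (degenerate profile matrix?)")
}

#' Consensus clustering of TF occupancy dynamics
#'
#' The normalized TF-by-condition profiles are clustered `nRuns` times with
#' randomly initialized K-means at every cluster number in `kRange`; the
#' co-clustering frequency `kappa(i, j)` is the fraction of all those runs
#' (pooled across k) in which TFs i and j share a cluster. `1 - kappa` is
#' then the distance in a final agglomerative clustering cut at `nFinal`
#' clusters.
#'
#' @param x A [TFOccupancyMatrix-class] (its normalized matrix is used) or a
#'   plain numeric matrix of TF profiles.
#' @param nRuns K-means runs per k (default 100).
#' @param kRange Cluster numbers (default 8:12).
#' @param nFinal Final number of clusters (default 10).
#' @param seed Integer master seed (bit-for-bit reproducible).
#' @param linkage Linkage of the final hierarchical step (default
#'   `"average"`).
#' @return A [ConsensusClustering-class].
#' @export
consensusCluster <- function(x, nRuns = 100, kRange = 8:12, nFinal = 10,
                             seed = 1, linkage = "average") {
  mat <- if (is(x, "TFOccupancyMatrix")) x@normalized else as.matrix(x)
  nt <- nrow(mat)
  if (nt < nFinal) stop("need at least ", nFinal, " TFs")
  if (anyNA(mat)) stop("TF profile matrix must be complete")
  co <- matrix(0, nt, nt)
  total <- 0L
  withr::with_seed(seed, {
    for (k in kRange) {
      for (r in seq_len(nRuns)) {
        cl <- .kmeansOnce(mat, k)
        co <- co + outer(cl, cl, `==`)
        total <- total + 1L
      }
    }
  })
  kappa <- co / total
  dimnames(kappa) <- list(rownames(mat), rownames(mat))
  hc <- stats::hclust(stats::as.dist(1 - kappa), method = linkage)
  labels <- stats::cutree(hc, k = nFinal)
  new("ConsensusClustering", kappa = kappa, labels = as.integer(labels),
      kRange = as.integer(kRange), nRuns = as.integer(nRuns),
      linkage = linkage)
}

#' Jaccard index of two regulons
#'
#' Size of the intersection of the two gene sets divided by the size of their
#' union; 0 (flagged by attribute `"empty"`) when both are empty.
#'
#' @param a,b Character vectors of gene names.
#' @return Numeric scalar in [0, 1].
#' @export
jaccardRegulons <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) { out <- 0; attr(out, "empty") <- TRUE; return(out) }
  length(intersect(a, b)) / length(u)
}
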