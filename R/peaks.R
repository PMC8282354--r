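# Ricker (Mexican-hat) wavelet kernel of scale `a` bins, centered at index 1
# of a length-n circular vector (so FFT convolution yields a centered
# response).
.rickerKernel <- function(n, a) {
  h <- min(ceiling(10 * a), floor((n - 1) / 2))
  t <- (-h):h
  A <- 2 / (sqrt(3 * a) * pi^0.25)
  psi <- A * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
  k <- numeric(n)
  k[(t %% n) + 1] <- psi
  k
}

# CWT coefficient matrix (scales x positions) by circular FFT convolution.
.cwtRicker <- function(x, scales) {
  n <- length(x)
  fx <- stats::fft(x)
  t(vapply(scales, function(a) {
    fk <- stats::fft(.rickerKernel(n, a))
    Re(stats::fft(fx * fk, inverse = TRUE)) / n
  }, numeric(n)))
}

# Circular local maxima (strict neighbors) of one row of coefficients.
.localMaxima <- function(v) {
  n <- length(v)
  left <- v[c(n, seq_len(n - 1))]
  right <- v[c(seq_len(n)[-1], 1)]
  which(v > left & v > right)
}

# Link per-scale maxima into ridge lines, working from the largest scale
# down, with a positional tolerance of scale/4 bins and a gap tolerance in
# scales. Returns a list of ridges, each a matrix with columns (scaleIdx,
# pos).
.linkRidges <- function(maximaByScale, scales, n, gapThresh, circular = TRUE) {
  ns <- length(scales)
  circDist <- function(a, b) {
    d <- abs(a - b)
    if (circular) pmin(d, n - d) else d
  }
  active <- list()   # each: list(points = matrix, gap = int)
  done <- list()
  for (s in rev(seq_len(ns))) {
    mx <- maximaByScale[[s]]
    claimed <- logical(length(mx))
    keepActive <- list()
    for (rg in active) {
      lastPos <- rg$points[nrow(rg$points), 2]
      if (length(mx)) {
        d <- circDist(mx, lastPos)
        cand <- which(!claimed & d <= max(scales[s] / 4, 1))
      } else cand <- integer()
      if (length(cand)) {
        j <- cand[which.min(circDist(mx[cand], lastPos))]
        claimed[j] <- TRUE
        rg$points <- rbind(rg$points, c(s, mx[j]))
        rg$gap <- 0L
        keepActive[[length(keepActive) + 1L]] <- rg
      } else {
        rg$gap <- rg$gap + 1L
        if (rg$gap > gapThresh) done[[length(done) + 1L]] <- rg
        else keepActive[[length(keepActive) + 1L]] <- rg
      }
    }
    for (j in which(!claimed)) {
      keepActive[[length(keepActive) + 1L]] <-
        list(points = matrix(c(s, mx[j]), nrow = 1), gap = 0L)
    }
    active <- keepActive
  }
  c(done, active)
}

#' Call occupancy peaks by continuous wavelet transform ridge detection
#'
#' Transcription-factor-scale peaks are detected on the robust-z occupancy
#' track with a Mexican-hat (ricker) CWT over a ladder of widths (default 25
#' to 125 bp in 5-bp steps, matching the expected footprint sizes given input
#' DNA fragmentation). Per-scale local maxima are linked into ridge lines
#' (positional tolerance width/4 bins, gap tolerance `gapThresh` scales);
#' ridges spanning at least a quarter of the width ladder are scored by a
#' signal-to-noise ratio: the ridge's maximum coefficient (the response at
#' its matched scale) divided by the magnitude of the `noisePerc` (signed)
#' percentile of the smallest-width coefficients in a centered
#' `noiseWindowBins`-bin window around the apex. Each
#' surviving ridge becomes one peak call, labeled with the most stringent
#' supplied threshold its SNR passes; the apex is expanded to the detected
#' width and padded by `padBp` on each side.
#'
#' @param z Robust-z [GenomeTrack-class].
#' @param widthsBp Width ladder in bp.
#' @param snrThresholds Ascending SNR calling thresholds.
#' @param padBp Padding added to each side of the raw call (default 30 bp).
#' @param gapThresh Ridge gap tolerance in scales.
#' @param minRidgeFrac Minimum ridge length as a fraction of the ladder.
#' @param noiseWindowBins Window (bins) for the local noise floor.
#' @param noisePerc Quantile of |coefficients| used as noise floor.
#' @return A data.frame with one row per peak: `apexBp`, `widthBp`, `snr`,
#'   `minSnrThreshold`, `rawStart`, `rawEnd`, `start`, `end` (padded;
#'   wrapping intervals have `start > end`).
#' @export
callPeaksCwt <- function(z, widthsBp = seq(25, 125, by = 5),
                         snrThresholds = c(2, 3, 4, 6, 8, 10),
                         padBp = 30, gapThresh = 2, minRidgeFrac = 0.25,
                         noiseWindowBins = 1000, noisePerc = 0.10) {
  res <- z@resolution
  n <- nBins(z)
  L <- z@genomeLength
  scales <- widthsBp / res
  if (any(scales != round(scales))) {
    warning("widths not multiples of the track resolution; rounding to whole bins")
    scales <- pmax(1, round(scales))
  }
  scales <- unique(scales)
  snrThresholds <- sort(snrThresholds)
  x <- z@values
  x[is.na(x)] <- 0
  coefs <- .cwtRicker(x, scales)
  maximaByScale <- lapply(seq_along(scales), function(s) .localMaxima(coefs[s, ]))
  ridges <- .linkRidges(maximaByScale, scales, n, gapThresh, z@circular)
  minLen <- ceiling(length(scales) * minRidgeFrac)
  ridges <- Filter(function(r) nrow(r$points) >= minLen, ridges)
  if (length(ridges) == 0) return(.emptyPeaks())
  half <- floor(noiseWindowBins / 2)
  row1 <- coefs[1, ]
  rows <- lapply(ridges, function(r) {
    pts <- r$points
    cf <- coefs[cbind(pts[, 1], pts[, 2])]
    i <- which.max(cf)
    apexBin <- pts[i, 2]
    widthBp <- scales[pts[i, 1]] * res
    # signal = the ridge's maximum coefficient (its matched scale); noise
    # floor = magnitude of the (signed) noisePerc percentile of the
    # smallest-width coefficients in a centered window around the apex --
    # for zero-mean noise this percentile is negative and its magnitude
    # tracks the local coefficient scale
    win <- ((apexBin - half):(apexBin + half) - 1) %% n + 1
    noise <- stats::quantile(row1[win], noisePerc, names = FALSE)
    snr <- abs(cf[i]) / max(abs(noise), .Machine$double.eps)
    data.frame(apexBp = (apexBin - 1) * res + res / 2, widthBp = widthBp,
               snr = snr)
  })
  pk <- do.call(rbind, rows)
  pk <- pk[pk$snr >= snrThresholds[1], , drop = FALSE]
  if (nrow(pk) == 0) return(.emptyPeaks())
  pk$minSnrThreshold <- vapply(pk$snr, function(s) {
    max(snrThresholds[snrThresholds <= s])
  }, numeric(1))
  rawStart <- round(pk$apexBp - pk$widthBp / 2)
  pk$rawStart <- rawStart %% L
  pk$rawEnd <- (rawStart + pk$widthBp) %% L
  pk$rawEnd[pk$rawEnd == 0] <- L
  pk$start <- (rawStart - padBp) %% L
  pk$end <- (rawStart + pk$widthBp + padBp) %% L
  pk$end[pk$end == 0] <- L
  pk <- pk[order(pk$rawStart), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

.emptyPeaks <- function() {
  data.frame(apexBp = numeric(), widthBp = numeric(), snr = numeric(),
             minSnrThreshold = numeric(), rawStart = numeric(),
             rawEnd = numeric(), start = numeric(), end = numeric())
}

#' Peak set at one calling threshold
#'
#' Restricts calls to those whose SNR passes the threshold and merges
#' overlapping padded intervals within the set; a merged peak keeps the
#' minimum threshold label, the strongest apex, and the maximum SNR.
#'
#' @param peaks Data.frame from [callPeaksCwt()].
#' @param threshold SNR calling threshold.
#' @param genomeLength Genome length in bp (for wrap-aware merging).
#' @return Data.frame of merged peak calls at this threshold.
#' @export
peaksAtThreshold <- function(peaks, threshold, genomeLength) {
  pk <- peaks[peaks$snr >= threshold, , drop = FALSE]
  if (nrow(pk) <= 1) { rownames(pk) <- NULL; return(pk) }
  L <- genomeLength
  s <- pk$start
  e <- ifelse(pk$end > pk$start, pk$end, pk$end + L)  # unroll wraps
  ord <- order(s, e)
  pk <- pk[ord, , drop = FALSE]; s <- s[ord]; e <- e[ord]
  grp <- integer(nrow(pk)); g <- 1L; grp[1] <- g; ce <- e[1]
  for (i in seq_len(nrow(pk))[-1]) {
    if (s[i] < ce) { grp[i] <- g; ce <- max(ce, e[i]) }
    else { g <- g + 1L; grp[i] <- g; ce <- e[i] }
  }
  merged <- lapply(split(seq_len(nrow(pk)), grp), function(idx) {
    sub <- pk[idx, , drop = FALSE]
    best <- which.max(sub$snr)
    data.frame(apexBp = sub$apexBp[best], widthBp = sub$widthBp[best],
               snr = max(sub$snr), minSnrThreshold = min(sub$minSnrThreshold),
               rawStart = sub$rawStart[best], rawEnd = sub$rawEnd[best],
               start = min(s[idx]) %% L, end = max(e[idx]) %% L)
  })
  out <- do.call(rbind, merged)
  out$end[out$end == 0] <- L
  rownames(out) <- NULL
  out
}

#' Attach mean and discretized scores to peak calls
#'
#' `meanZ` is the mean robust z over the raw (unpadded) call; the discrete
#' score used for motif discovery is `floor(meanZ)`. Peaks with negative mean
#' are retained but flagged by `discreteScore < 0` (they are excluded from
#' motif-preparation exports).
#'
#' @param peaks Data.frame from [callPeaksCwt()] / [peaksAtThreshold()].
#' @param z Robust-z [GenomeTrack-class].
#' @return The data.frame with `meanZ` and `discreteScore` columns added.
#' @export
scorePeaks <- function(peaks, z) {
  if (nrow(peaks) == 0) {
    peaks$meanZ <- numeric(); peaks$discreteScore <- numeric()
    return(peaks)
  }
  peaks$meanZ <- vapply(seq_len(nrow(peaks)), function(i) {
    bins <- binsForInterval(peaks$rawStart[i], peaks$rawEnd[i], z)
    mean(z@values[bins], na.rm = TRUE)
  }, numeric(1))
  peaks$discreteScore <- floor(peaks$meanZ)
  if (any(peaks$discreteScore < 0))
    warning(sum(peaks$discreteScore < 0),
            " peak(s) have negative mean z; they will be dropped from motif exports")
  peaks
}

#' Convert peak calls to a GenomeFeatures interval set
#'
#' The score column carries the calling threshold label, matching the
#' convention used for exported peak GFF files.
#'
#' @param peaks Data.frame of peak calls.
#' @param genomeLength Genome length in bp.
#' @param chrom Chromosome name.
#' @param padded Use padded (`TRUE`, default) or raw intervals.
#' @return A [GenomeFeatures-class].
#' @export
peaksToFeatures <- function(peaks, genomeLength, chrom = "genome", padded = TRUE) {
  if (nrow(peaks) == 0)
    return(GenomeFeatures(genomeLength = genomeLength, chrom = chrom))
  s <- if (padded) peaks$start else peaks$rawStart
  e <- if (padded) peaks$end else peaks$rawEnd
  GenomeFeatures(s, e, genomeLength, score = peaks$minSnrThreshold,
                 name = sprintf("peak_%d", seq_len(nrow(peaks))),
                 source = "cwt", chrom = chrom)
}

#' Enrichment of annotated sites under peak calls
#'
#' The observed fraction of annotated sites overlapping at least one peak is
#' compared with its expectation under random circular rotations of the site
#' coordinates; enrichment is the ratio of observed to mean rotated fraction,
#' and the p-value comes from the rotation permutation test.
#'
#' @param peaks A [GenomeFeatures-class] of peak calls.
#' @param sites A [GenomeFeatures-class] of annotated sites.
#' @param genomeLength Genome length in bp.
#' @param nPerm Number of rotations.
#' @param seed Integer seed.
#' @return List with `enrichment`, `p`, `observed`, `expected`.
#' @export
peakSiteOverlap <- function(peaks, sites, genomeLength = NULL, nPerm = 200,
                            seed = 1) {
  L <- if (is.null(genomeLength)) peaks@genomeLength else genomeLength
  if (length(peaks) == 0 || length(sites) == 0)
    stop("both peak and site sets must be non-empty")
  pmask <- featureMask(peaks, L)
  fracOverlapping <- function(fs) {
    s <- fs@start; e <- fs@end
    hit <- vapply(seq_along(s), function(i) {
      if (e[i] > s[i]) any(pmask[(s[i] + 1):e[i]])
      else any(pmask[(s[i] + 1):L]) || (e[i] > 0 && any(pmask[1:e[i]]))
    }, logical(1))
    mean(hit)
  }
  rt <- rotationPermutationTest(sites, fracOverlapping, nPerm, seed)
  expected <- mean(rt$permuted)
  list(enrichment = rt$observed / expected, p = rt$p,
       observed = rt$observed, expected = expected)
}
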