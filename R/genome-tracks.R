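#' Test whether two tracks live on the same bin grid
#'
#' Tracks are "aligned" iff chromosome, genome length and resolution match.
#'
#' @param a,b [GenomeTrack-class] objects.
#' @return Logical scalar.
#' @export
tracksAligned <- function(a, b) {
  identical(a@chrom, b@chrom) &&
    a@genomeLength == b@genomeLength &&
    a@resolution == b@resolution
}

.stopifnotAligned <- function(tracks) {
  if (length(tracks) < 2) return(invisible(TRUE))
  ref <- tracks[[1]]
  for (i in seq_along(tracks)[-1]) {
    if (!tracksAligned(ref, tracks[[i]]))
      stop("tracks are not aligned (chrom/genomeLength/resolution differ)")
  }
  invisible(TRUE)
}

#' Centered circular rolling mean of a track
#'
#' The window is `round(windowBp / resolution)` bins, forced odd by adding one
#' bin when even, centered on each bin and wrapping across the origin on
#' circular chromosomes. Missing bins are excluded from each window's mean; a
#' window with no usable bins yields `NA`. On non-circular tracks positions
#' beyond the ends are treated as missing (the window shrinks at the edges).
#'
#' @param track A [GenomeTrack-class].
#' @param windowBp Window size in base pairs (>= resolution).
#' @return A [GenomeTrack-class] of the same geometry.
#' @export
rollingMeanCircular <- function(track, windowBp) {
  res <- track@resolution
  if (windowBp < res) stop("'windowBp' must be at least one bin (", res, " bp)")
  n <- nBins(track)
  w <- round(windowBp / res)
  if (w %% 2 == 0) w <- w + 1
  if (w > n) stop("rolling window (", w, " bins) exceeds the genome (", n, " bins)")
  x <- track@values
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  kern <- rep(1, w)
  if (track@circular) {
    num <- as.numeric(stats::filter(x0, kern, sides = 2, circular = TRUE))
    den <- as.numeric(stats::filter(as.numeric(ok), kern, sides = 2, circular = TRUE))
  } else {
    num <- as.numeric(stats::filter(x0, kern, sides = 2, circular = FALSE))
    den <- as.numeric(stats::filter(as.numeric(ok), kern, sides = 2, circular = FALSE))
    # linear filter leaves NAs at the edges; recompute there with shrunken windows
    h <- (w - 1) / 2
    edge <- c(seq_len(min(h, n)), seq.int(max(1, n - h + 1), n))
    for (i in unique(edge)) {
      lo <- max(1, i - h); hi <- min(n, i + h)
      num[i] <- sum(x0[lo:hi]); den[i] <- sum(ok[lo:hi])
    }
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  GenomeTrack(out, track@genomeLength, res, track@chrom, track@circular)
}

#' Base-pair occupancy mask of a feature set
#'
#' Logical vector of length `genomeLength`; `TRUE` where some interval covers
#' that base. Wrapping intervals (`start > end`) cover both arms.
#'
#' @param features A [GenomeFeatures-class].
#' @param genomeLength Optional override of the genome length.
#' @return Logical vector of length `genomeLength`.
#' @export
featureMask <- function(features, genomeLength = NULL) {
  L <- if (is.null(genomeLength)) features@genomeLength else genomeLength
  mask <- logical(L)
  s <- features@start; e <- features@end
  for (i in seq_along(s)) {
    if (e[i] > s[i]) {
      mask[(s[i] + 1):e[i]] <- TRUE
    } else {
      mask[(s[i] + 1):L] <- TRUE
      if (e[i] > 0) mask[1:e[i]] <- TRUE
    }
  }
  mask
}

#' Symmetrized base-pair overlap fraction between two interval sets
#'
#' Computes, at single-base resolution, the fraction of set `a`'s covered
#' bases also covered by `b`, the reverse fraction, and their average (the
#' symmetrized overlap used to compare EPOD sets between conditions).
#'
#' @param a,b [GenomeFeatures-class] sets on the same genome.
#' @param genomeLength Genome length in bp (defaults to that of `a`).
#' @return List with `symmetric`, `fracAinB`, `fracBinA`. An empty set's
#'   one-directional fraction is defined as 0 and flagged by attribute
#'   `"empty"` on the result.
#' @export
intervalOverlapFraction <- function(a, b, genomeLength = NULL) {
  L <- if (is.null(genomeLength)) a@genomeLength else genomeLength
  ma <- featureMask(a, L); mb <- featureMask(b, L)
  na <- sum(ma); nb <- sum(mb)
  fab <- if (na > 0) sum(ma & mb) / na else 0
  fba <- if (nb > 0) sum(ma & mb) / nb else 0
  out <- list(symmetric = (fab + fba) / 2, fracAinB = fab, fracBinA = fba)
  if (na == 0 || nb == 0) attr(out, "empty") <- TRUE
  out
}

#' Rotate a feature set around the circular genome
#'
#' All coordinates are shifted by one common offset modulo the genome length,
#' preserving the internal spacing and length of every interval; intervals
#' pushed across the origin become wrapping intervals (`start > end`).
#'
#' @param features A [GenomeFeatures-class].
#' @param offsetBp Shift in base pairs.
#' @return The rotated [GenomeFeatures-class].
#' @export
rotateFeatures <- function(features, offsetBp) {
  L <- features@genomeLength
  len <- featureLengths(features)
  s <- (features@start + offsetBp) %% L
  e <- (s + len) %% L
  # a full-genome interval becomes end == start (full wrap); an interval
  # ending exactly at the origin keeps end = L
  e[e == 0 & len < L] <- L
  GenomeFeatures(s, e, L, score = features@score, name = features@name,
                 source = features@source, chrom = features@chrom)
}

#' Circular rotation permutation test
#'
#' The null distribution is generated by rigidly rotating the feature
#' coordinates relative to the underlying data by a uniform random offset per
#' permutation, preserving the correlation structure of both. The p-value uses
#' the add-one estimator `p = (1 + #{perm >= obs}) / (1 + nPerm)` for the
#' greater-is-extreme direction.
#'
#' @param features A [GenomeFeatures-class].
#' @param statistic Function mapping a [GenomeFeatures-class] to a single
#'   finite number.
#' @param nPerm Number of random rotations (>= 1).
#' @param seed Integer seed (required; the test is reproducible).
#' @return List with `observed`, `p`, and the vector of `permuted` statistics.
#' @export
rotationPermutationTest <- function(features, statistic, nPerm, seed) {
  stopifnot(nPerm >= 1)
  observed <- statistic(features)
  if (!is.finite(observed)) stop("statistic is not finite on the observed features")
  L <- features@genomeLength
  perm <- withr::with_seed(seed, {
    offs <- sample.int(L, nPerm, replace = TRUE) - 1
    vapply(offs, function(o) {
      s <- statistic(rotateFeatures(features, o))
      if (!is.finite(s)) stop("statistic is not finite on a permutation (offset ", o, ")")
      s
    }, numeric(1))
  })
  list(observed = observed,
       p = (1 + sum(perm >= observed)) / (1 + nPerm),
       permuted = perm)
}

#' Merge overlapping or bookended intervals
#'
#' Intervals that overlap or abut (`end == next start`) are merged into one.
#' When `byName = TRUE`, merging happens only within groups of identical
#' `name` (used to merge binding sites of the same transcription factor).
#' Wrapping across the origin is handled. Scores of merged members are
#' combined with `max` (NA-tolerant).
#'
#' @param features A [GenomeFeatures-class].
#' @param byName Merge within name groups only.
#' @param bookended Also merge intervals that merely touch.
#' @return A merged [GenomeFeatures-class].
#' @export
mergeFeatures <- function(features, byName = FALSE, bookended = TRUE) {
  L <- features@genomeLength
  groups <- if (byName) split(seq_along(features@start), features@name)
            else list(seq_along(features@start))
  out <- lapply(groups, function(idx) .mergeOneGroup(features, idx, L, bookended))
  do.call(rbind, out) -> df
  if (is.null(df) || nrow(df) == 0)
    return(GenomeFeatures(genomeLength = L, chrom = features@chrom))
  GenomeFeatures(df$start, df$end, L, score = df$score, name = df$name,
                 source = df$source, chrom = features@chrom)
}

.mergeOneGroup <- function(features, idx, L, bookended) {
  if (length(idx) == 0) return(NULL)
  # unroll wrapping intervals onto [0, 2L) so ordinary interval merging applies
  s <- features@start[idx]; e <- features@end[idx]
  wrap <- e <= s
  e2 <- ifelse(wrap, e + L, e)
  ord <- order(s, e2)
  s <- s[ord]; e2 <- e2[ord]
  sc <- features@score[idx][ord]; nm <- features@name[idx][ord]
  src <- features@source[idx][ord]
  ms <- s[1]; me <- e2[1]; msc <- sc[1]; mnm <- nm[1]; msrc <- src[1]
  rows <- list()
  push <- function(ms, me, msc, mnm, msrc) {
    if (me > L && ms < L) { e0 <- me - L } else if (me > L) { ms <- ms - L; e0 <- me - L
    } else e0 <- me
    # store wrap as start > end
    data.frame(start = ms %% L, end = if (me > L) e0 else me,
               score = msc, name = mnm, source = msrc, stringsAsFactors = FALSE)
  }
  for (i in seq_along(s)[-1]) {
    touches <- if (bookended) s[i] <= me else s[i] < me
    if (touches) {
      me <- max(me, e2[i])
      msc <- if (is.na(msc)) sc[i] else if (is.na(sc[i])) msc else max(msc, sc[i])
    } else {
      rows[[length(rows) + 1L]] <- push(ms, me, msc, mnm, msrc)
      ms <- s[i]; me <- e2[i]; msc <- sc[i]; mnm <- nm[i]; msrc <- src[i]
    }
  }
  rows[[length(rows) + 1L]] <- push(ms, me, msc, mnm, msrc)
  df <- do.call(rbind, rows)
  # circular closure: the last run may reach the origin (end == L, or a
  # wrapped end arm) and touch/overlap the first run
  if (nrow(df) >= 2) {
    nlast <- nrow(df)
    lastEndArm <- if (df$end[nlast] <= df$start[nlast]) df$end[nlast]
                  else if (df$end[nlast] == L) 0 else NA_real_
    if (!is.na(lastEndArm)) {
      touches <- if (bookended) df$start[1] <= lastEndArm
                 else df$start[1] < lastEndArm
      if (touches) {
        df$end[1] <- max(df$end[1], lastEndArm)
        df$start[1] <- df$start[nlast]
        df$score[1] <- suppressWarnings(max(df$score[1], df$score[nlast], na.rm = TRUE))
        df <- df[-nlast, , drop = FALSE]
      }
    }
  }
  df
}

#' Bin indices covered by an interval (wrap-aware)
#'
#' Returns the 1-based indices of the bins of an aligned track that overlap
#' the 0-based half-open interval `[start, end)`; `start > end` wraps.
#'
#' @param start,end Interval coordinates in bp.
#' @param track A [GenomeTrack-class] providing the bin grid.
#' @return Integer vector of bin indices.
#' @export
binsForInterval <- function(start, end, track) {
  res <- track@resolution; n <- nBins(track)
  span <- function(s, e) {
    if (e <= s) return(integer())
    lo <- floor(s / res) + 1
    hi <- ceiling(e / res)
    seq.int(lo, min(hi, n))
  }
  if (end > start) span(start, end)
  else c(span(start, track@genomeLength), span(0, end))
}
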