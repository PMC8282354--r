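#' Quantile normalize a set of aligned replicate tracks
#'
#' After normalization every track has the same sorted value vector: the
#' across-track mean of the sorted input values. Ties receive the mean of the
#' reference values they span. Normalization acts within one sample type of
#' one biological condition. A single track is returned unchanged.
#'
#' @param tracks List of aligned [GenomeTrack-class] replicates.
#' @return List of normalized tracks (same order).
#' @export
quantileNormalize <- function(tracks) {
  if (is(tracks, "GenomeTrack")) tracks <- list(tracks)
  .stopifnotAligned(tracks)
  if (length(tracks) < 2) return(tracks)
  mat <- vapply(tracks, binValues, numeric(nBins(tracks[[1]])))
  qn <- limma::normalizeQuantiles(mat, ties = TRUE)
  lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]; t@values <- qn[, i]; t
  })
}

#' Fit a periodic smoothing spline to the replication-gradient of a track
#'
#' Models the smooth ori-to-ter DNA abundance gradient of a replicating
#' circular chromosome: a cyclic cubic smoothing spline with `nKnots` evenly
#' spaced knots (at 0, L/4, L/2, 3L/4 for the default 4) and periodic boundary
#' conditions, with the smoothing penalty chosen by generalized
#' cross-validation. Missing bins are imputed as the track median before
#' fitting. Fitted values are floored at a small positive epsilon; if more
#' than 1% of bins hit the floor the fit is rejected.
#'
#' @param track Input-sample [GenomeTrack-class] (replicate-averaged).
#' @param nKnots Number of distinct evenly spaced knots (default 4).
#' @param smoothing Optional fixed smoothing parameter (`sp` of [mgcv::gam()]);
#'   `NULL` (default) selects it by GCV.
#' @param eps Positivity floor for the fitted values.
#' @return A [GenomeTrack-class] holding the smoothed abundance, with
#'   attribute `"floored"` giving the number of floored bins.
#' @export
fitPeriodicSpline <- function(track, nKnots = 4, smoothing = NULL, eps = 1e-8) {
  v <- binValues(track)
  if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
  n <- length(v)
  L <- track@genomeLength
  x <- (seq_len(n) - 0.5) * track@resolution
  kn <- seq(0, L, length.out = nKnots + 1)
  dat <- data.frame(y = v, x = x)
  fit <- mgcv::gam(y ~ s(x, bs = "cc", k = nKnots + 1), data = dat,
                   knots = list(x = kn), sp = smoothing)
  pred <- as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
  floored <- sum(pred < eps)
  if (floored > 0.01 * n)
    stop("periodic spline fit is non-positive on ", floored, " bins (> 1%)")
  pred <- pmax(pred, eps)
  out <- GenomeTrack(pred, L, track@resolution, track@chrom, track@circular)
  attr(out, "floored") <- floored
  out
}

#' Divide all tracks of a condition by the input-derived abundance spline
#'
#' Corrects for copy-number variation along the chromosome (the ori-ter
#' replication gradient): every replicate track of every sample type is
#' divided bin-wise by the smoothed abundance of the condition's input sample.
#'
#' @param bundle A [ConditionBundle-class] whose replicates have been quantile
#'   normalized.
#' @param spline Optional precomputed spline track; by default it is fitted to
#'   the replicate-averaged input with [fitPeriodicSpline()].
#' @param nKnots,smoothing Passed to [fitPeriodicSpline()].
#' @return The bundle with corrected replicates and `derived$spline` set.
#' @export
copyNumberCorrect <- function(bundle, spline = NULL, nKnots = 4, smoothing = NULL) {
  if (is.null(spline)) {
    inputAvg <- averageReplicates(bundle@input)
    spline <- fitPeriodicSpline(inputAvg, nKnots = nKnots, smoothing = smoothing)
  }
  sv <- binValues(spline)
  if (any(sv == 0)) stop("spline track contains zeros")
  div <- function(t) { t@values <- t@values / sv; t }
  bundle@input <- lapply(bundle@input, div)
  bundle@ipod <- lapply(bundle@ipod, div)
  bundle@chip <- lapply(bundle@chip, div)
  bundle@derived$spline <- spline
  bundle
}

#' Rescale tracks to a common mean
#'
#' Each track is multiplied by (grand mean of the track means) / (its own
#' mean), so all outputs share the same mean signal level.
#'
#' @param tracks List of aligned [GenomeTrack-class] objects.
#' @return List of rescaled tracks.
#' @export
matchMeans <- function(tracks) {
  if (is(tracks, "GenomeTrack")) tracks <- list(tracks)
  .stopifnotAligned(tracks)
  mns <- vapply(tracks, function(t) mean(t@values, na.rm = TRUE), numeric(1))
  if (any(mns <= 0)) stop("all track means must be positive for mean matching")
  grand <- mean(mns)
  lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]; t@values <- t@values * (grand / mns[i]); t
  })
}

#' Bin-wise average of replicate tracks
#'
#' Missing-aware arithmetic mean: a bin's average uses the replicates that
#' observed it; a bin missing in all replicates stays missing.
#'
#' @param tracks List of aligned [GenomeTrack-class] replicates.
#' @return A single averaged [GenomeTrack-class].
#' @export
averageReplicates <- function(tracks) {
  if (is(tracks, "GenomeTrack")) tracks <- list(tracks)
  .stopifnotAligned(tracks)
  mat <- vapply(tracks, binValues, numeric(nBins(tracks[[1]])))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(tracks))
  out <- tracks[[1]]
  out@values <- rowMeans(mat, na.rm = TRUE)
  out@values[is.nan(out@values)] <- NA_real_
  out
}

#' Log2 ratio of an extracted track to its input
#'
#' `log2((extracted + pseudocount) / (input + pseudocount))`. Bins missing in
#' either argument are missing in the output. The default pseudocount is 0:
#' after quantile normalization and mean matching the values are strictly
#' positive in practice.
#'
#' @param extracted,input Aligned [GenomeTrack-class] objects.
#' @param pseudocount Non-negative stabilizer added to both arguments.
#' @return A [GenomeTrack-class] of log2 ratios.
#' @export
log2Ratio <- function(extracted, input, pseudocount = 0) {
  .stopifnotAligned(list(extracted, input))
  e <- extracted@values + pseudocount
  i <- input@values + pseudocount
  if (any(e < 0, na.rm = TRUE) || any(i < 0, na.rm = TRUE))
    stop("negative values after normalization; check the pipeline or use a pseudocount")
  out <- extracted
  out@values <- log2(e / i)
  out@values[is.na(i)] <- NA_real_
  out
}

#' Run the full normalization chain on a condition
#'
#' Applies, in order: quantile normalization within each sample type;
#' copy-number correction by the periodic spline fitted to the averaged input;
#' rescaling of all tracks to a common mean; replicate averaging per sample
#' type; and log2 extracted:input ratios. The derived tracks are stored in
#' `bundle@derived` (`spline`, `inputAvg`, `ipodAvg`, `chipAvg`, `ipodLog2`,
#' `chipLog2`).
#'
#' @param bundle A raw [ConditionBundle-class].
#' @param nKnots,smoothing Spline parameters (see [fitPeriodicSpline()]).
#' @param pseudocount Passed to [log2Ratio()].
#' @return The bundle with all derived tracks filled in.
#' @export
normalizeCondition <- function(bundle, nKnots = 4, smoothing = NULL,
                               pseudocount = 0) {
  bundle@input <- quantileNormalize(bundle@input)
  bundle@ipod <- quantileNormalize(bundle@ipod)
  bundle@chip <- quantileNormalize(bundle@chip)
  bundle <- copyNumberCorrect(bundle, nKnots = nKnots, smoothing = smoothing)
  nin <- length(bundle@input); nip <- length(bundle@ipod)
  all_tracks <- matchMeans(c(bundle@input, bundle@ipod, bundle@chip))
  bundle@input <- all_tracks[seq_len(nin)]
  bundle@ipod <- all_tracks[nin + seq_len(nip)]
  bundle@chip <- all_tracks[(nin + nip + 1):length(all_tracks)]
  bundle@derived$inputAvg <- averageReplicates(bundle@input)
  bundle@derived$ipodAvg <- averageReplicates(bundle@ipod)
  bundle@derived$chipAvg <- averageReplicates(bundle@chip)
  bundle@derived$ipodLog2 <- log2Ratio(bundle@derived$ipodAvg, bundle@derived$inputAvg, pseudocount)
  bundle@derived$chipLog2 <- log2Ratio(bundle@derived$chipAvg, bundle@derived$inputAvg, pseudocount)
  bundle
}
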