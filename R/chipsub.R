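#' Fit the RNA polymerase subtraction slope
#'
#' The high-ChIP subpopulation (top `topFrac` of bins by ChIP log2 signal) is
#' presumed to be bound entirely by RNA polymerase. The model is the
#' zero-intercept line of lowest possible non-negative slope that keeps
#' `coverFrac` of those bins at or below it in the (ChIP, IPOD) plane. With
#' positive ChIP values this is an order statistic of the per-bin ratios
#' ipod/chip: the smallest ratio `r` with `#{ratio <= r} >= ceiling(coverFrac
#' * n)`. A point exactly on the line counts as below (non-above).
#'
#' @param ipodLog2,chipLog2 Aligned log2 ratio tracks.
#' @param topFrac Fraction of usable bins, ranked by ChIP signal, entering the
#'   fit (default 0.02).
#' @param coverFrac Fraction of fit points the line must cover (default 0.95).
#' @return A [ChipSubModel-class].
#' @export
fitSubtractionSlope <- function(ipodLog2, chipLog2, topFrac = 0.02,
                                coverFrac = 0.95) {
  .stopifnotAligned(list(ipodLog2, chipLog2))
  ip <- ipodLog2@values; ch <- chipLog2@values
  usable <- which(!is.na(ip) & !is.na(ch))
  nFit <- as.integer(ceiling(topFrac * length(usable)))
  top <- usable[order(ch[usable], decreasing = TRUE)[seq_len(nFit)]]
  pos <- top[ch[top] > 0]
  if (length(pos) < 20)
    stop("fewer than 20 positive-ChIP bins in the top-", topFrac, " set; cannot fit slope")
  ratios <- ip[pos] / ch[pos]
  bad <- !is.finite(ratios)
  if (any(bad)) {
    message(sum(bad), " non-finite ipod/chip ratios excluded from the slope fit")
    ratios <- ratios[!bad]
  }
  m <- length(ratios)
  k <- ceiling(coverFrac * m)
  slope <- sort(ratios)[k]
  new("ChipSubModel", slope = max(slope, 0), topFrac = topFrac,
      coverFrac = coverFrac, nFitPoints = nFit)
}

#' Subtract the RNA polymerase contribution from the IPOD signal
#'
#' At bins with positive observed ChIP occupancy, `slope * chip` is removed
#' from the IPOD log2 signal; no subtraction is performed where the observed
#' RNA polymerase occupancy is non-positive, so the correction can only lower
#' (never raise) occupancy.
#'
#' @param ipodLog2,chipLog2 Aligned log2 ratio tracks.
#' @param model A fitted [ChipSubModel-class].
#' @return The corrected occupancy [GenomeTrack-class].
#' @export
subtractRnap <- function(ipodLog2, chipLog2, model) {
  .stopifnotAligned(list(ipodLog2, chipLog2))
  ip <- ipodLog2@values; ch <- chipLog2@values
  out <- ipodLog2
  sub <- !is.na(ch) & ch > 0
  out@values[sub] <- ip[sub] - model@slope * ch[sub]
  out
}

#' Robust z standardization of a track
#'
#' `z_i = (x_i - median(X)) / mad(X)`, with `mad` the raw median absolute
#' deviation `median(|x - median(X)|)` without any normal-consistency scaling
#' factor, over non-missing bins.
#'
#' @param track A [GenomeTrack-class].
#' @return A [GenomeTrack-class] with median 0 and MAD 1.
#' @export
robustZ <- function(track) {
  x <- track@values
  med <- stats::median(x, na.rm = TRUE)
  m <- stats::mad(x, constant = 1, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("MAD of the track is zero; cannot standardize")
  out <- track
  out@values <- (x - med) / m
  out
}

#' Upper-tail -log10 p-values for robust z-scores
#'
#' Under the null that robust z-scores are standard normal, returns
#' `-log10 P(Z >= z)` (one-sided, enrichment direction), computed through the
#' log of the complementary tail so precision is retained for large z.
#'
#' @param z A robust-z [GenomeTrack-class] (or plain numeric vector).
#' @return Same shape as the input, values >= 0 for z >= ~-0.5 and always
#'   finite.
#' @export
neglog10Pvalues <- function(z) {
  f <- function(v) -stats::pnorm(v, lower.tail = FALSE, log.p = TRUE) / log(10)
  if (is(z, "GenomeTrack")) {
    out <- z
    out@values <- f(z@values)
    out
  } else f(z)
}

#' Score one condition: subtraction, robust z, tail p-values
#'
#' Runs the scoring chain on a normalized bundle: fit the subtraction slope on
#' the condition's averaged log2 tracks, subtract, standardize to robust z,
#' and convert to upper-tail -log10 p-values.
#'
#' @param bundle A [ConditionBundle-class] processed by
#'   [normalizeCondition()].
#' @param topFrac,coverFrac Passed to [fitSubtractionSlope()].
#' @param replicateInterval If `TRUE`, also compute the pessimistic
#'   replicate-combination interval with [replicateExtremeInterval()].
#' @param combinationCap Passed on when `replicateInterval` is `TRUE`.
#' @return A [ScoredProfile-class].
#' @export
scoreCondition <- function(bundle, topFrac = 0.02, coverFrac = 0.95,
                           replicateInterval = FALSE, combinationCap = 64) {
  d <- bundle@derived
  if (is.null(d$ipodLog2) || is.null(d$chipLog2))
    stop("bundle has no log2 ratio tracks; run normalizeCondition() first")
  model <- fitSubtractionSlope(d$ipodLog2, d$chipLog2, topFrac, coverFrac)
  cs <- subtractRnap(d$ipodLog2, d$chipLog2, model)
  z <- robustZ(cs)
  p <- neglog10Pvalues(z)
  lo <- hi <- NULL
  if (replicateInterval) {
    li <- replicateExtremeInterval(bundle, topFrac = topFrac,
                                   coverFrac = coverFrac, cap = combinationCap)
    lo <- li$lo; hi <- li$hi
  }
  new("ScoredProfile", condition = bundle@condition, chipsub = cs,
      robustZ = z, neglog10p = p, replicateLo = lo, replicateHi = hi,
      model = model)
}

#' Pessimistic replicate-combination interval of the occupancy statistic
#'
#' For every combination of one IPOD, one ChIP, and one input replicate, the
#' full scoring pipeline (log2 ratios, slope fit, subtraction, robust z,
#' -log10 p) is recomputed from the copy-number-corrected, mean-matched
#' replicate tracks; the per-bin minimum and maximum of the resulting -log10 p
#' statistic bound the values any replicate choice could have produced.
#'
#' @param bundle A [ConditionBundle-class] processed by
#'   [normalizeCondition()] (so replicates are normalized in place).
#' @param topFrac,coverFrac Slope-fit parameters.
#' @param cap Maximum number of combinations (error beyond; default 64).
#' @return List of two aligned tracks, `lo` and `hi`.
#' @export
replicateExtremeInterval <- function(bundle, topFrac = 0.02, coverFrac = 0.95,
                                     cap = 64) {
  combos <- expand.grid(i = seq_along(bundle@ipod), c = seq_along(bundle@chip),
                        n = seq_along(bundle@input))
  if (nrow(combos) > cap)
    stop(nrow(combos), " replicate combinations exceed the cap (", cap,
         "); subsample replicates or raise 'cap'")
  stats_mat <- vapply(seq_len(nrow(combos)), function(r) {
    ip <- log2Ratio(bundle@ipod[[combos$i[r]]], bundle@input[[combos$n[r]]])
    ch <- log2Ratio(bundle@chip[[combos$c[r]]], bundle@input[[combos$n[r]]])
    model <- fitSubtractionSlope(ip, ch, topFrac, coverFrac)
    z <- robustZ(subtractRnap(ip, ch, model))
    neglog10Pvalues(z)@values
  }, numeric(nBins(bundle@ipod[[1]])))
  lo <- bundle@ipod[[1]]; hi <- bundle@ipod[[1]]
  lo@values <- apply(stats_mat, 1, min)
  hi@values <- apply(stats_mat, 1, max)
  list(lo = lo, hi = hi)
}
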