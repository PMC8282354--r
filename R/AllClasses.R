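#' @import methods
NULL

#' GenomeTrack: a binned signal track on a (circular) bacterial chromosome
#'
#' A `GenomeTrack` holds one real value per fixed-width bin along a single
#' chromosome. Bins are laid out 0-based: bin `i` covers
#' `[i * resolution, (i + 1) * resolution)` base pairs, with the final bin
#' truncated at `genomeLength` when the resolution does not divide the genome
#' length. Missing signal is stored as `NA`. Tracks flagged `circular` wrap
#' across the origin for all rolling statistics.
#'
#' @slot chrom Chromosome identifier.
#' @slot genomeLength Genome length in base pairs.
#' @slot resolution Bin width in base pairs (default used throughout: 5).
#' @slot values Numeric vector, one value per bin (`NA` = missing).
#' @slot circular Logical; whether the chromosome is circular.
#'
#' @examples
#' tr <- GenomeTrack(values = rnorm(20), genomeLength = 100, resolution = 5)
#' nBins(tr)
#' @export
setClass("GenomeTrack",
  representation(
    chrom = "character",
    genomeLength = "numeric",
    resolution = "numeric",
    values = "numeric",
    circular = "logical"
  )
)

setValidity("GenomeTrack", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L) msg <- c(msg, "'chrom' must be length 1")
  if (length(object@genomeLength) != 1L || object@genomeLength <= 0)
    msg <- c(msg, "'genomeLength' must be a single positive number")
  if (length(object@resolution) != 1L || object@resolution <= 0)
    msg <- c(msg, "'resolution' must be a single positive number")
  nb <- ceiling(object@genomeLength / object@resolution)
  if (length(object@values) != nb)
    msg <- c(msg, sprintf("number of bins must be ceiling(genomeLength / resolution) = %d, got %d",
                          nb, length(object@values)))
  if (any(is.infinite(object@values)))
    msg <- c(msg, "track values must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeTrack
#'
#' @param values Numeric vector of per-bin values (`NA` allowed).
#' @param genomeLength Genome length in bp.
#' @param resolution Bin width in bp.
#' @param chrom Chromosome name.
#' @param circular Whether the chromosome is circular.
#' @return A [GenomeTrack-class] object.
#' @export
GenomeTrack <- function(values, genomeLength, resolution = 5,
                        chrom = "genome", circular = TRUE) {
  new("GenomeTrack",
      chrom = as.character(chrom),
      genomeLength = as.numeric(genomeLength),
      resolution = as.numeric(resolution),
      values = as.numeric(values),
      circular = isTRUE(circular))
}

#' GenomeFeatures: genomic intervals with scores on a circular chromosome
#'
#' Intervals are 0-based half-open `[start, end)`. On a circular chromosome an
#' interval may wrap the origin, in which case it is stored unwrapped with
#' `start > end` (it covers `[start, genomeLength)` followed by `[0, end)`).
#' Intervals are kept sorted by `start`.
#'
#' @slot chrom Chromosome identifier.
#' @slot genomeLength Genome length in bp.
#' @slot start Integer-valued starts (0-based, inclusive).
#' @slot end Integer-valued ends (exclusive); `end < start` marks a wrap.
#' @slot score Per-interval numeric score (`NA` allowed).
#' @slot name Per-interval name.
#' @slot source Per-interval provenance tag.
#' @export
setClass("GenomeFeatures",
  representation(
    chrom = "character",
    genomeLength = "numeric",
    start = "numeric",
    end = "numeric",
    score = "numeric",
    name = "character",
    source = "character"
  )
)

setValidity("GenomeFeatures", function(object) {
  msg <- character()
  n <- length(object@start)
  if (length(object@end) != n || length(object@score) != n ||
      length(object@name) != n || length(object@source) != n)
    msg <- c(msg, "per-interval attribute vectors must all have the same length")
  L <- object@genomeLength
  if (n > 0) {
    if (any(object@start < 0 | object@start >= L))
      msg <- c(msg, "starts must satisfy 0 <= start < genomeLength")
    if (any(object@end < 0 | object@end > L))
      msg <- c(msg, "ends must satisfy 0 <= end <= genomeLength")
    len <- ifelse(object@end > object@start,
                  object@end - object@start,
                  L - object@start + object@end)
    if (any(len <= 0)) msg <- c(msg, "all intervals must have positive length")
    if (is.unsorted(object@start)) msg <- c(msg, "intervals must be sorted by start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeFeatures interval set
#'
#' @param start,end 0-based half-open coordinates; `start > end` wraps the
#'   origin on a circular chromosome.
#' @param genomeLength Genome length in bp.
#' @param score,name,source Optional per-interval attributes (recycled).
#' @param chrom Chromosome name.
#' @return A [GenomeFeatures-class] object sorted by start.
#' @export
GenomeFeatures <- function(start = numeric(), end = numeric(), genomeLength,
                           score = NA_real_, name = NA_character_,
                           source = NA_character_, chrom = "genome") {
  n <- length(start)
  score <- rep_len(as.numeric(score), n)
  name <- rep_len(as.character(name), n)
  source <- rep_len(as.character(source), n)
  ord <- order(start, end)
  new("GenomeFeatures",
      chrom = as.character(chrom), genomeLength = as.numeric(genomeLength),
      start = as.numeric(start)[ord], end = as.numeric(end)[ord],
      score = score[ord], name = name[ord], source = source[ord])
}

#' ChipSubModel: the RNA polymerase subtraction line
#'
#' Zero-intercept line fitted to the high-ChIP subpopulation of the
#' (ChIP log2, IPOD log2) scatter: the lowest non-negative slope keeping
#' `coverFrac` of the top-`topFrac` ChIP bins at or below the line.
#'
#' @slot slope Fitted slope (>= 0).
#' @slot topFrac Fraction of bins (by ChIP signal rank) used for the fit.
#' @slot coverFrac Fraction of fit points the line must keep non-above.
#' @slot nFitPoints Number of bins in the top-ChIP fit set.
#' @export
setClass("ChipSubModel",
  representation(slope = "numeric", topFrac = "numeric",
                 coverFrac = "numeric", nFitPoints = "integer"))

setValidity("ChipSubModel", function(object) {
  msg <- character()
  if (object@slope < 0) msg <- c(msg, "'slope' must be >= 0")
  if (object@topFrac <= 0 || object@topFrac > 1) msg <- c(msg, "'topFrac' must be in (0, 1]")
  if (object@coverFrac <= 0 || object@coverFrac >= 1) msg <- c(msg, "'coverFrac' must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' ConditionBundle: all tracks for one biological condition
#'
#' Holds the per-replicate input, IPOD interphase, and RNA polymerase ChIP
#' tracks for one biological condition, plus derived tracks filled in by the
#' normalization chain (copy-number spline, replicate averages, log2
#' extracted:input ratios).
#'
#' @slot condition Condition label.
#' @slot input,ipod,chip Lists of aligned [GenomeTrack-class] replicates.
#' @slot derived Named list of derived tracks (`spline`, `inputAvg`,
#'   `ipodAvg`, `chipAvg`, `ipodLog2`, `chipLog2`) and per-replicate
#'   intermediates.
#' @export
setClass("ConditionBundle",
  representation(condition = "character", input = "list",
                 ipod = "list", chip = "list", derived = "list"))

setValidity("ConditionBundle", function(object) {
  msg <- character()
  all_tracks <- c(object@input, object@ipod, object@chip)
  if (length(object@input) < 1 || length(object@ipod) < 1 || length(object@chip) < 1)
    msg <- c(msg, "at least one replicate per sample type is required")
  if (!all(vapply(all_tracks, is, logical(1), "GenomeTrack")))
    msg <- c(msg, "replicates must be GenomeTrack objects")
  else if (length(all_tracks) > 1) {
    ref <- all_tracks[[1]]
    ok <- vapply(all_tracks, function(t) tracksAligned(ref, t), logical(1))
    if (!all(ok)) msg <- c(msg, "all replicate tracks must be aligned (same chrom, genomeLength, resolution)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ConditionBundle
#'
#' @param input,ipod,chip Lists of aligned [GenomeTrack-class] replicates (a
#'   single track may be given bare).
#' @param condition Condition label.
#' @return A [ConditionBundle-class].
#' @export
ConditionBundle <- function(input, ipod, chip, condition = "condition") {
  as_list <- function(x) if (is(x, "GenomeTrack")) list(x) else x
  new("ConditionBundle", condition = as.character(condition),
      input = as_list(input), ipod = as_list(ipod), chip = as_list(chip),
      derived = list())
}

#' ScoredProfile: RNA-polymerase-corrected occupancy scores
#'
#' The fully processed occupancy signal for one condition: the ChIP-subtracted
#' log2 occupancy, its robust z standardization, the upper-tail -log10
#' p-values, and (optionally) pessimistic replicate-combination bounds on the
#' -log10 p scale.
#'
#' @slot condition Condition label.
#' @slot chipsub Corrected log2 occupancy [GenomeTrack-class].
#' @slot robustZ Robust z-scores (median 0, MAD 1).
#' @slot neglog10p Upper-tail standard-normal -log10 p-values (>= 0).
#' @slot replicateLo,replicateHi Per-bin extremes of the -log10 p statistic
#'   over all replicate combinations (`NULL` until computed).
#' @slot model The fitted [ChipSubModel-class] (or `NULL`).
#' @export
setClass("ScoredProfile",
  representation(condition = "character", chipsub = "GenomeTrack",
                 robustZ = "GenomeTrack", neglog10p = "GenomeTrack",
                 replicateLo = "ANY", replicateHi = "ANY", model = "ANY"))

#' TFOccupancyMatrix: TF-by-condition occupancy summary
#'
#' Geometric-mean site-level occupancy per transcription factor and condition,
#' with the row-normalized version on (0, 1] used for clustering.
#'
#' @slot scores TF x condition matrix of geometric-mean -log10 p occupancies.
#' @slot normalized `scores` with each row divided by its maximum.
#' @slot nSites Number of detectable sites per TF.
#' @export
setClass("TFOccupancyMatrix",
  representation(scores = "matrix", normalized = "matrix", nSites = "integer"))

setValidity("TFOccupancyMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@scores), dim(object@normalized)))
    msg <- c(msg, "'scores' and 'normalized' must have identical dimensions")
  if (nrow(object@scores) > 0 && any(object@scores <= 0, na.rm = TRUE))
    msg <- c(msg, "scores must be strictly positive (floor applied upstream)")
  if (nrow(object@normalized) > 0) {
    rm <- apply(object@normalized, 1, max, na.rm = TRUE)
    if (any(abs(rm - 1) > 1e-8)) msg <- c(msg, "normalized row maxima must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusClustering: co-clustering frequencies and final labels
#'
#' @slot kappa Symmetric TF x TF co-clustering frequency matrix in [0, 1]
#'   (unit diagonal), pooled over all K-means runs.
#' @slot labels Named integer vector of final cluster assignments.
#' @slot kRange Cluster numbers used for the K-means runs.
#' @slot nRuns K-means runs per cluster number.
#' @slot linkage Linkage used in the final hierarchical step.
#' @export
setClass("ConsensusClustering",
  representation(kappa = "matrix", labels = "integer", kRange = "integer",
                 nRuns = "integer", linkage = "character"))

setValidity("ConsensusClustering", function(object) {
  msg <- character()
  k <- object@kappa
  if (nrow(k) != ncol(k)) msg <- c(msg, "'kappa' must be square")
  else {
    if (max(abs(k - t(k))) > 1e-12) msg <- c(msg, "'kappa' must be symmetric")
    if (any(abs(diag(k) - 1) > 1e-12)) msg <- c(msg, "'kappa' diagonal must be 1")
    if (any(k < 0 | k > 1)) msg <- c(msg, "'kappa' entries must lie in [0, 1]")
  }
  if (length(object@labels) != nrow(k)) msg <- c(msg, "one label per TF required")
  if (length(msg)) msg else TRUE
})
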