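#' @rdname GenomeTrack-class
#' @param object,x A track or feature object.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname GenomeTrack-class
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname GenomeTrack-class
#' @param value Replacement values.
#' @export
setGeneric("binValues<-", function(x, value) standardGeneric("binValues<-"))

#' @rdname GenomeTrack-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname GenomeTrack-class
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))

#' @rdname GenomeTrack-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname GenomeFeatures-class
#' @export
setGeneric("featureStarts", function(x) standardGeneric("featureStarts"))

#' @rdname GenomeFeatures-class
#' @export
setGeneric("featureEnds", function(x) standardGeneric("featureEnds"))

#' @rdname GenomeFeatures-class
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))

#' @rdname GenomeFeatures-class
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' @rdname GenomeFeatures-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

setMethod("nBins", "GenomeTrack", function(x) length(x@values))
setMethod("binValues", "GenomeTrack", function(x) x@values)
setMethod("binValues<-", "GenomeTrack", function(x, value) {
  x@values <- as.numeric(value)
  validObject(x)
  x
})
setMethod("genomeLength", "GenomeTrack", function(x) x@genomeLength)
setMethod("binResolution", "GenomeTrack", function(x) x@resolution)
setMethod("isCircular", "GenomeTrack", function(x) x@circular)
setMethod("length", "GenomeTrack", function(x) length(x@values))

setMethod("genomeLength", "GenomeFeatures", function(x) x@genomeLength)
setMethod("length", "GenomeFeatures", function(x) length(x@start))
setMethod("featureStarts", "GenomeFeatures", function(x) x@start)
setMethod("featureEnds", "GenomeFeatures", function(x) x@end)
setMethod("featureLengths", "GenomeFeatures", function(x) {
  ifelse(x@end > x@start, x@end - x@start, x@genomeLength - x@start + x@end)
})
setMethod("featureScores", "GenomeFeatures", function(x) x@score)
setMethod("featureNames", "GenomeFeatures", function(x) x@name)

setMethod("show", "GenomeTrack", function(object) {
  v <- object@values
  cat(sprintf("GenomeTrack on %s%s: %d bins x %g bp (genome %g bp)\n",
              object@chrom, if (object@circular) " (circular)" else "",
              length(v), object@resolution, object@genomeLength))
  cat(sprintf("  non-missing: %d/%d; range: [%.4g, %.4g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "GenomeFeatures", function(object) {
  cat(sprintf("GenomeFeatures on %s (genome %g bp): %d intervals\n",
              object@chrom, object@genomeLength, length(object@start)))
  n <- min(5L, length(object@start))
  if (n > 0) {
    df <- data.frame(start = object@start[seq_len(n)], end = object@end[seq_len(n)],
                     score = object@score[seq_len(n)], name = object@name[seq_len(n)])
    print(df, row.names = FALSE)
    if (length(object@start) > n) cat(sprintf("  ... and %d more\n", length(object@start) - n))
  }
})

setMethod("show", "ChipSubModel", function(object) {
  cat(sprintf("ChipSubModel: slope = %.4g (top %.3g%% of ChIP bins, %d fit points, cover %.3g)\n",
              object@slope, 100 * object@topFrac, object@nFitPoints, object@coverFrac))
})

setMethod("show", "ConditionBundle", function(object) {
  cat(sprintf("ConditionBundle '%s': %d input / %d ipod / %d chip replicates; derived: %s\n",
              object@condition, length(object@input), length(object@ipod),
              length(object@chip),
              if (length(object@derived)) paste(names(object@derived), collapse = ", ")
              else "<none>"))
})

setMethod("show", "ScoredProfile", function(object) {
  cat(sprintf("ScoredProfile '%s' (%d bins)\n", object@condition, nBins(object@robustZ)))
  if (!is.null(object@model)) show(object@model)
  if (!is.null(object@replicateLo)) cat("  replicate-extreme interval: present\n")
})

setMethod("show", "TFOccupancyMatrix", function(object) {
  cat(sprintf("TFOccupancyMatrix: %d TFs x %d conditions\n",
              nrow(object@scores), ncol(object@scores)))
})

setMethod("show", "ConsensusClustering", function(object) {
  cat(sprintf("ConsensusClustering: %d TFs, %d clusters (k in %s, %d runs each, %s linkage)\n",
              nrow(object@kappa), length(unique(object@labels)),
              paste(range(object@kRange), collapse = ".."),
              object@nRuns, object@linkage))
})
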