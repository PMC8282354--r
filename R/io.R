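#' Read a bedGraph file onto a track's bin grid
#'
#' bedGraph records are interpreted 0-based half-open. Every base covered by a
#' record takes that record's value; bins are then summarized as the mean over
#' their covered bases, and bins with no coverage become missing (`NA`).
#' Overlapping records or records extending beyond the genome are errors.
#'
#' @param path bedGraph file path.
#' @param genomeLength Genome length in bp.
#' @param resolution Bin width in bp.
#' @param chrom Chromosome name for the resulting track (defaults to the one
#'   in the file, or "genome" for an empty file).
#' @param circular Circularity flag of the resulting track.
#' @param format Only `"bedgraph"` is supported.
#' @return A [GenomeTrack-class].
#' @export
readTrack <- function(path, genomeLength, resolution = 5, chrom = NULL,
                      circular = TRUE, format = "bedgraph") {
  format <- match.arg(tolower(format), "bedgraph")
  L <- as.integer(genomeLength)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) {
    n <- ceiling(genomeLength / resolution)
    return(GenomeTrack(rep(NA_real_, n), genomeLength, resolution,
                       chrom = if (is.null(chrom)) "genome" else chrom,
                       circular = circular))
  }
  s <- GenomicRanges::start(gr) - 1L  # back to 0-based
  e <- GenomicRanges::end(gr)
  v <- gr$score
  if (any(e > L)) {
    bad <- which(e > L)[1]
    stop(sprintf("record %d ([%d,%d)) extends beyond genomeLength = %d", bad, s[bad], e[bad], L))
  }
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]; v <- v[ord]
  if (length(s) > 1) {
    coll <- which(s[-1] < e[-length(e)])
    if (length(coll)) {
      i <- coll[1]
      stop(sprintf("overlapping bedGraph records: [%d,%d) collides with [%d,%d)",
                   s[i], e[i], s[i + 1], e[i + 1]))
    }
  }
  # base-pair accumulation, then bin means over covered bases
  bp <- rep(NA_real_, L)
  for (i in seq_along(s)) bp[(s[i] + 1):e[i]] <- v[i]
  n <- ceiling(genomeLength / resolution)
  binid <- rep(seq_len(n), each = resolution, length.out = L)
  covered <- !is.na(bp)
  sums <- rowsum(bp[covered], binid[covered])
  cnts <- rowsum(rep(1, sum(covered)), binid[covered])
  vals <- rep(NA_real_, n)
  vals[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  GenomeTrack(vals, genomeLength, resolution,
              chrom = if (is.null(chrom)) as.character(GenomicRanges::seqnames(gr))[1] else chrom,
              circular = circular)
}

#' Write a track as bedGraph
#'
#' Adjacent bins with equal values are merged into a single record; missing
#' bins are emitted as gaps. The final record is truncated at the genome
#' length when the resolution does not divide it.
#'
#' @param track A [GenomeTrack-class].
#' @param path Output path.
#' @param format Only `"bedgraph"` is supported.
#' @export
writeTrack <- function(track, path, format = "bedgraph") {
  format <- match.arg(tolower(format), "bedgraph")
  v <- track@values
  res <- track@resolution
  # run-length encode, treating NA as its own (skipped) run
  key <- ifelse(is.na(v), "NA", format(v, digits = 17))
  r <- rle(key)
  endsBin <- cumsum(r$lengths)
  startsBin <- endsBin - r$lengths
  keep <- r$values != "NA"
  s <- startsBin[keep] * res
  e <- pmin(endsBin[keep] * res, track@genomeLength)
  vals <- v[endsBin[keep]]  # value of any bin in the run
  if (length(s) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(track@chrom, IRanges::IRanges(start = s + 1, end = e),
                               score = vals)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read genomic features from GFF3, BED, or TSV
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; BED is already 0-based half-open and kept as is. The
#' TSV format expects a header with columns `start`, `end` (0-based
#' half-open) and optional `score`, `name`, `source`.
#'
#' @param path Input file.
#' @param format One of `"gff3"`, `"bed"`, `"tsv"`.
#' @param genomeLength Genome length in bp.
#' @param chrom Chromosome name override.
#' @return A [GenomeFeatures-class].
#' @export
readFeatures <- function(path, format = c("gff3", "bed", "tsv"), genomeLength,
                         chrom = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                   error = function(e) stop("malformed TSV: ", conditionMessage(e)))
    need <- c("start", "end")
    if (!all(need %in% names(df)))
      stop("TSV feature file must have 'start' and 'end' columns")
    return(GenomeFeatures(df$start, df$end, genomeLength,
                          score = if ("score" %in% names(df)) df$score else NA_real_,
                          name = if ("name" %in% names(df)) df$name else NA_character_,
                          source = if ("source" %in% names(df)) df$source else NA_character_,
                          chrom = if (is.null(chrom)) "genome" else chrom))
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (length(gr) == 0)
    return(GenomeFeatures(genomeLength = genomeLength,
                          chrom = if (is.null(chrom)) "genome" else chrom))
  s <- GenomicRanges::start(gr) - 1L   # both GFF and rtracklayer's parsed BED are 1-based here
  e <- GenomicRanges::end(gr)
  md <- S4Vectors::mcols(gr)
  nm <- if (!is.null(md$Name)) as.character(md$Name)
        else if (!is.null(md$name)) as.character(md$name)
        else if (!is.null(md$ID)) as.character(md$ID) else NA_character_
  sc <- if (!is.null(md$score)) as.numeric(md$score) else NA_real_
  src <- if (!is.null(md$source)) as.character(md$source) else NA_character_
  GenomeFeatures(s, e, genomeLength, score = sc, name = nm, source = src,
                 chrom = if (is.null(chrom)) as.character(GenomicRanges::seqnames(gr))[1] else chrom)
}

#' Write genomic features as GFF3, BED, or TSV
#'
#' Internal 0-based half-open coordinates are converted to 1-based inclusive
#' for GFF3 and left as is for BED/TSV. Intervals wrapping the origin are
#' split into their two arms for GFF3/BED output (they share a name); the TSV
#' format writes them unsplit with `start > end`.
#'
#' @param features A [GenomeFeatures-class].
#' @param path Output path.
#' @param format One of `"gff3"`, `"bed"`, `"tsv"`.
#' @param type GFF3 feature type string.
#' @export
writeFeatures <- function(features, path, format = c("gff3", "bed", "tsv"),
                          type = "region") {
  format <- match.arg(format)
  L <- features@genomeLength
  s <- features@start; e <- features@end
  sc <- features@score; nm <- features@name; src <- features@source
  if (format == "tsv") {
    df <- data.frame(chrom = features@chrom, start = s, end = e,
                     score = sc, name = nm, source = src)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  wrap <- which(e <= s)
  if (length(wrap)) {
    s <- c(s[-wrap], s[wrap], rep(0, length(wrap)))
    e2 <- c(e[-wrap], rep(L, length(wrap)), e[wrap])
    sc <- c(sc[-wrap], sc[wrap], sc[wrap])
    nm <- c(nm[-wrap], nm[wrap], nm[wrap])
    src <- c(src[-wrap], src[wrap], src[wrap])
    e <- e2
  }
  if (length(s) == 0) { writeLines(character(), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(features@chrom, IRanges::IRanges(start = s + 1, end = e))
  gr$score <- sc
  if (!all(is.na(nm))) gr$Name <- nm
  if (format == "gff3") {
    gr$type <- type
    if (!all(is.na(src))) gr$source <- src
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    if (!all(is.na(nm))) gr$name <- nm
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}
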