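.extractSeq <- function(genome, start, end, L) {
  # genome: a Biostrings::DNAString (or character); 0-based half-open coords,
  # wrap-aware on the circular chromosome
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  if (end > start) {
    as.character(Biostrings::subseq(genome, start + 1, end))
  } else {
    paste0(as.character(Biostrings::subseq(genome, start + 1, L)),
           as.character(Biostrings::subseq(genome, 1, end)))
  }
}

#' Build a scored sequence dataset for motif discovery
#'
#' Emits one record per scored peak (sequence plus its discrete occupancy
#' score) together with a background of unbound sequences drawn from the
#' portion of the genome not covered by any peak: `bgMultiple` times as many
#' records as peaks, matching the peak length distribution exactly (each peak
#' length appears `bgMultiple` times), all with score 0.
#'
#' @param peaks Scored peak data.frame (see [scorePeaks()]); peaks with
#'   negative discrete score are dropped with a warning.
#' @param genome Genome sequence ([Biostrings::DNAString] or character).
#' @param genomeLength Genome length in bp (defaults to `nchar(genome)`).
#' @param bgMultiple Background records per peak (default 3).
#' @param seed Integer seed for background sampling.
#' @param maxAttempts Rejection-sampling attempts per background record.
#' @return Data.frame with `name`, `start`, `end`, `sequence`, `score`;
#'   peak records first, then background.
#' @export
buildFireDataset <- function(peaks, genome, genomeLength = NULL,
                             bgMultiple = 3, seed = 1, maxAttempts = 10000) {
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  L <- if (is.null(genomeLength)) length(genome) else genomeLength
  if (is.null(peaks$discreteScore)) stop("peaks must be scored (see scorePeaks)")
  neg <- peaks$discreteScore < 0
  if (any(neg)) {
    warning(sum(neg), " negative-score peak(s) dropped from the motif dataset")
    peaks <- peaks[!neg, , drop = FALSE]
  }
  if (nrow(peaks) == 0) stop("no non-negative-score peaks to export")
  s <- peaks$start; e <- peaks$end
  lens <- ifelse(e > s, e - s, L - s + e)
  pmask <- featureMask(GenomeFeatures(s, e, L), L)
  free <- which(!pmask) - 1  # 0-based candidate start positions
  bgLens <- rep(lens, each = bgMultiple)
  bg <- withr::with_seed(seed, {
    lapply(bgLens, function(len) {
      for (a in seq_len(maxAttempts)) {
        st <- free[sample.int(length(free), 1)]
        en <- (st + len) %% L
        idx <- if (en > st) (st + 1):en else c((st + 1):L, seq_len(max(en, 0)))
        if (!any(pmask[idx])) return(c(st, if (en == 0) L else en))
      }
      stop("could not place a background record of length ", len,
           " after ", maxAttempts, " attempts")
    })
  })
  bgs <- vapply(bg, `[`, numeric(1), 1)
  bge <- vapply(bg, `[`, numeric(1), 2)
  pk <- data.frame(
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    start = s, end = e,
    sequence = vapply(seq_along(s), function(i) .extractSeq(genome, s[i], e[i], L), character(1)),
    score = peaks$discreteScore)
  bgdf <- data.frame(
    name = sprintf("background_%d", seq_along(bgs)),
    start = bgs, end = bge,
    sequence = vapply(seq_along(bgs), function(i) .extractSeq(genome, bgs[i], bge[i], L), character(1)),
    score = 0)
  rbind(pk, bgdf)
}

#' Write a motif-discovery dataset as two-column sequence/score text
#'
#' @param dataset From [buildFireDataset()].
#' @param path Output path.
#' @export
writeFireDataset <- function(dataset, path) {
  utils::write.table(dataset[, c("sequence", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Circular-permutation decoy peak sets
#'
#' Each decoy rigidly rotates the peak coordinates by one uniform random
#' offset modulo the genome length (equivalently, rotating the genome
#' sequence under the peaks), preserving peak count, lengths, scores, and the
#' correlation structure among peaks.
#'
#' @param peaks Scored peak data.frame.
#' @param genomeLength Genome length in bp.
#' @param n Number of decoys (default 20).
#' @param seed Integer seed.
#' @return List with `offsets` (bp) and `peakSets` (list of data.frames).
#' @export
makeDecoys <- function(peaks, genomeLength, n = 20, seed = 1) {
  stopifnot(n >= 1)
  L <- genomeLength
  offsets <- withr::with_seed(seed, sample.int(L, n, replace = TRUE) - 1)
  peakSets <- lapply(offsets, function(o) {
    pk <- peaks
    lens <- ifelse(pk$end > pk$start, pk$end - pk$start, L - pk$start + pk$end)
    pk$start <- (pk$start + o) %% L
    pk$end <- (pk$start + lens) %% L
    pk$end[pk$end == 0] <- L
    if (!is.null(pk$rawStart)) {
      rl <- ifelse(pk$rawEnd > pk$rawStart, pk$rawEnd - pk$rawStart,
                   L - pk$rawStart + pk$rawEnd)
      pk$rawStart <- (pk$rawStart + o) %% L
      pk$rawEnd <- (pk$rawStart + rl) %% L
      pk$rawEnd[pk$rawEnd == 0] <- L
    }
    pk
  })
  list(offsets = offsets, peakSets = peakSets)
}

#' False discovery rate estimate from decoy motif counts
#'
#' The maximum motif count discovered across the decoy datasets divided by
#' the count discovered in the real data (floored at 1).
#'
#' @param realCount Motifs discovered in the real dataset.
#' @param decoyCounts Motifs discovered in each decoy dataset.
#' @return FDR estimate; flagged degenerate (attribute `"degenerate"`) when
#'   `realCount` is 0.
#' @export
motifFdr <- function(realCount, decoyCounts) {
  stopifnot(realCount >= 0, length(decoyCounts) >= 1)
  out <- max(decoyCounts) / max(realCount, 1)
  if (realCount == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Assign predicted regulons to motifs by TSS proximity
#'
#' A transcriptional unit is regulated by a motif iff some predicted binding
#' site for that motif lies within `windowBp` of the unit's annotated
#' transcription start site (circular distance between the hit interval and
#' the TSS position; 0 if the TSS falls inside the hit). The genes of all
#' included units are unioned per motif.
#'
#' @param motifHits [GenomeFeatures-class] of predicted binding sites,
#'   `name` = motif id.
#' @param tss Data.frame with columns `pos` (0-based TSS position), `tu`
#'   (transcriptional unit), and `genes` (comma-separated gene names), or a
#'   [GenomeFeatures-class] whose starts are TSS positions and names carry
#'   `tu|gene1,gene2` strings.
#' @param windowBp Inclusive distance cutoff (default 100).
#' @param genomeLength Genome length in bp.
#' @return Named list: motif id -> character vector of genes.
#' @export
assignRegulons <- function(motifHits, tss, windowBp = 100, genomeLength = NULL) {
  L <- if (is.null(genomeLength)) motifHits@genomeLength else genomeLength
  if (is(tss, "GenomeFeatures")) {
    parts <- strsplit(tss@name, "|", fixed = TRUE)
    tss <- data.frame(pos = tss@start,
                      tu = vapply(parts, `[`, character(1), 1),
                      genes = vapply(parts, function(p) p[2], character(1)))
  }
  circDistToInterval <- function(pos, s, e) {
    # distance from point to 0-based half-open [s, e) on the circle
    len <- if (e > s) e - s else L - s + e
    rel <- (pos - s) %% L
    if (rel < len) return(0)
    gap_after <- rel - len + 1      # bp past the interval end
    gap_before <- L - rel           # bp before the interval start
    min(gap_after, gap_before)
  }
  motifs <- unique(motifHits@name)
  out <- stats::setNames(vector("list", length(motifs)), motifs)
  for (m in motifs) {
    idx <- which(motifHits@name == m)
    genes <- character()
    for (t in seq_len(nrow(tss))) {
      d <- min(vapply(idx, function(i) {
        circDistToInterval(tss$pos[t], motifHits@start[i], motifHits@end[i])
      }, numeric(1)))
      if (d <= windowBp)
        genes <- union(genes, strsplit(tss$genes[t], ",", fixed = TRUE)[[1]])
    }
    out[[m]] <- genes
  }
  out
}
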