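#' Specify the ground truth for a synthetic condition
#'
#' Describes everything the generator plants: the circular genome, the smooth
#' ori-to-ter copy-number gradient, narrow transcription-factor peaks (with
#' per-condition on/off states), RNA polymerase peaks that appear in both the
#' ChIP and the interphase signal (coupled by `couplingSlope`), kilobase-scale
#' occupancy plateaus (EPODs), and the log-normal replicate noise level.
#'
#' Feature tables are data.frames with columns `start`, `end` (0-based
#' half-open bp), `amplitude` (multiplicative effect size), and optionally
#' `conditions` (";"-separated condition names, or "all").
#'
#' @param genomeLength Genome length in bp (default 500 kb: a desk-scale
#'   genome the full pipeline processes in seconds).
#' @param resolution Bin width in bp.
#' @param oriPosition Origin of replication (bp).
#' @param gradientFold Ori/ter abundance ratio (>= 1, default 2).
#' @param tfPeaks,rnapPeaks,epods Feature tables (possibly empty).
#' @param couplingSlope Strength of the RNA polymerase contribution to the
#'   interphase signal relative to the ChIP signal (default 1.2).
#' @param noiseSigma Log-scale (sdlog) replicate noise (default 0.01,
#'   emulating deeply sequenced 5-bp bins).
#' @param baseDepth Mean signal level of the input track.
#' @return A list of class `"SyntheticTruth"`.
#' @export
syntheticTruth <- function(genomeLength = 5e5, resolution = 5,
                           oriPosition = 0, gradientFold = 2,
                           tfPeaks = NULL, rnapPeaks = NULL, epods = NULL,
                           couplingSlope = 1.2, noiseSigma = 0.01,
                           baseDepth = 100) {
  stopifnot(gradientFold >= 1, noiseSigma >= 0)
  emptyFeat <- data.frame(start = numeric(), end = numeric(),
                          amplitude = numeric(), conditions = character())
  fixFeat <- function(f) {
    if (is.null(f) || nrow(f) == 0) return(emptyFeat)
    if (is.null(f$conditions)) f$conditions <- "all"
    f
  }
  truth <- list(genomeLength = genomeLength, resolution = resolution,
                oriPosition = oriPosition, gradientFold = gradientFold,
                tfPeaks = fixFeat(tfPeaks), rnapPeaks = fixFeat(rnapPeaks),
                epods = fixFeat(epods), couplingSlope = couplingSlope,
                noiseSigma = noiseSigma, baseDepth = baseDepth)
  class(truth) <- "SyntheticTruth"
  truth
}

#' Randomly placed synthetic truth
#'
#' Places non-overlapping TF peaks, RNA polymerase peaks, and EPOD plateaus
#' on the genome with the requested counts and size/amplitude ranges.
#'
#' @param genomeLength,resolution,gradientFold,couplingSlope,noiseSigma
#'   Passed to [syntheticTruth()].
#' @param nTf,nRnap,nEpod Feature counts.
#' @param tfWidthBp,tfAmplitude,rnapWidthBp,rnapAmplitude,epodWidthBp,epodAmplitude
#'   Ranges (length-2) to draw sizes and multiplicative amplitudes from.
#' @param conditions Condition names; each TF peak is active in a random
#'   non-empty subset ("all" with probability 1/2).
#' @param seed Integer seed.
#' @return A `"SyntheticTruth"` list.
#' @export
randomSyntheticTruth <- function(genomeLength = 5e5, resolution = 5,
                                 gradientFold = 2, couplingSlope = 1.2,
                                 noiseSigma = 0.01,
                                 nTf = 30, nRnap = 20, nEpod = 4,
                                 tfWidthBp = c(50, 150), tfAmplitude = c(2, 6),
                                 rnapWidthBp = c(200, 1000), rnapAmplitude = c(2, 8),
                                 epodWidthBp = c(2000, 6000), epodAmplitude = c(0.8, 1.5),
                                 conditions = "synthetic", seed = 1) {
  withr::with_seed(seed, {
    placed <- matrix(numeric(0), ncol = 2)
    placeSet <- function(k, widthRange) {
      out <- matrix(numeric(0), ncol = 2)
      tries <- 0
      while (nrow(out) < k && tries < 10000) {
        tries <- tries + 1
        w <- round(stats::runif(1, widthRange[1], widthRange[2]))
        s <- sample.int(genomeLength - w, 1)  # avoid wrapping for simplicity
        e <- s + w
        all_iv <- rbind(placed, out)
        clear <- all(apply(all_iv, 1, function(iv) e + 200 <= iv[1] || s >= iv[2] + 200)) ||
          nrow(all_iv) == 0
        if (clear) out <- rbind(out, c(s, e))
      }
      if (nrow(out) < k) stop("could not place all features; genome too crowded")
      placed <<- rbind(placed, out)
      out
    }
    ep <- placeSet(nEpod, epodWidthBp)
    rn <- placeSet(nRnap, rnapWidthBp)
    tf <- placeSet(nTf, tfWidthBp)
    condSubset <- function() {
      if (length(conditions) == 1 || stats::runif(1) < 0.5) return("all")
      k <- sample.int(length(conditions) - 1, 1)
      paste(sample(conditions, k), collapse = ";")
    }
    mk <- function(m, ampRange, withCond = FALSE) {
      if (nrow(m) == 0) return(NULL)
      data.frame(start = m[, 1], end = m[, 2],
                 amplitude = stats::runif(nrow(m), ampRange[1], ampRange[2]),
                 conditions = if (withCond) vapply(seq_len(nrow(m)), function(i) condSubset(), character(1))
                              else "all")
    }
    syntheticTruth(genomeLength = genomeLength, resolution = resolution,
                   gradientFold = gradientFold, couplingSlope = couplingSlope,
                   noiseSigma = noiseSigma,
                   tfPeaks = mk(tf, tfAmplitude, withCond = TRUE),
                   rnapPeaks = mk(rn, rnapAmplitude),
                   epods = mk(ep, epodAmplitude))
  })
}

# Per-bin multiplicative bump profile for one feature class. TF and RNAP
# peaks are Gaussian (sd = width/4); EPOD plateaus are boxcars.
.bumpProfile <- function(feat, n, res, L, condition, shape = c("gauss", "box")) {
  shape <- match.arg(shape)
  prof <- numeric(n)
  if (is.null(feat) || nrow(feat) == 0) return(prof)
  active <- vapply(feat$conditions, function(cs) {
    cs == "all" || condition %in% strsplit(cs, ";", fixed = TRUE)[[1]]
  }, logical(1))
  x <- (seq_len(n) - 0.5) * res
  for (i in which(active)) {
    s <- feat$start[i]; e <- feat$end[i]; a <- feat$amplitude[i]
    if (shape == "box") {
      bins <- unique(pmin(pmax(floor(s / res) + 1, 1), n):pmin(ceiling(e / res), n))
      prof[bins] <- prof[bins] + a
    } else {
      mid <- (s + e) / 2; sd <- (e - s) / 4
      d <- abs(x - mid); d <- pmin(d, L - d)
      sel <- d < 5 * sd
      prof[sel] <- prof[sel] + a * exp(-d[sel]^2 / (2 * sd^2))
    }
  }
  prof
}

#' Generate the tracks (or fragments) of one synthetic condition
#'
#' Emulates the three-subpopulation structure the pipeline assumes: the input
#' follows the smooth copy-number gradient; the RNA polymerase ChIP track
#' carries the gradient plus RNAP peaks; and the interphase (IPOD) track
#' carries the gradient plus `couplingSlope` times the RNAP peaks, the active
#' TF peaks, and the EPOD plateaus. Each replicate is multiplied by
#' independent per-bin log-normal noise. With `output = "fragments"`,
#' per-bin fragment counts are Poisson with intensity proportional to the
#' track, fragment lengths uniform on 50-200 bp, and the returned bundle is
#' built by [fragmentOccupancy()].
#'
#' @param truth A `"SyntheticTruth"` list.
#' @param condition Condition name (determines which TF peaks are active).
#' @param nReplicates Named vector: replicates per sample type.
#' @param output `"tracks"` (default) or `"fragments"`.
#' @param seed Integer seed; outputs are bit-identical for a fixed seed.
#' @param meanFragsPerBin Mean fragment count per bin for fragment output.
#' @return A [ConditionBundle-class]; attribute `"truth"` carries the truth,
#'   attribute `"fragments"` the fragment sets when requested.
#' @export
generateCondition <- function(truth, condition = "synthetic",
                              nReplicates = c(input = 2, ipod = 2, chip = 2),
                              output = c("tracks", "fragments"), seed = 1,
                              meanFragsPerBin = 2) {
  output <- match.arg(output)
  L <- truth$genomeLength; res <- truth$resolution
  n <- ceiling(L / res)
  x <- (seq_len(n) - 0.5) * res
  theta <- 2 * pi * (x - truth$oriPosition) / L
  grad <- exp(log(truth$gradientFold) / 2 * cos(theta))
  rnap <- .bumpProfile(truth$rnapPeaks, n, res, L, condition, "gauss")
  tf <- .bumpProfile(truth$tfPeaks, n, res, L, condition, "gauss")
  ep <- .bumpProfile(truth$epods, n, res, L, condition, "box")
  base <- list(
    input = truth$baseDepth * grad,
    chip = truth$baseDepth * grad * (1 + rnap),
    ipod = truth$baseDepth * grad * (1 + truth$couplingSlope * rnap + tf + ep))
  fragments <- list()
  mkTracks <- withr::with_seed(seed, {
    lapply(c("input", "ipod", "chip"), function(type) {
      lapply(seq_len(nReplicates[[type]]), function(r) {
        mu <- base[[type]] * exp(stats::rnorm(n, 0, truth$noiseSigma))
        if (output == "tracks") {
          GenomeTrack(mu, L, res, chrom = "synthetic", circular = TRUE)
        } else {
          lambda <- meanFragsPerBin * mu / mean(mu)
          cnt <- stats::rpois(n, lambda)
          tot <- sum(cnt)
          mid <- rep(x, cnt) + stats::runif(tot, -res / 2, res / 2)
          len <- round(stats::runif(tot, 50, 200))
          s <- round(mid - len / 2) %% L
          e <- (s + len) %% L
          e[e == 0] <- L
          frags <- GenomeFeatures(s, e, L, chrom = "synthetic")
          fragments[[paste0(type, "_", r)]] <<- frags
          fragmentOccupancy(frags, resolution = res)
        }
      })
    })
  })
  names(mkTracks) <- c("input", "ipod", "chip")
  bundle <- ConditionBundle(mkTracks$input, mkTracks$ipod, mkTracks$chip,
                            condition = condition)
  attr(bundle, "truth") <- truth
  if (output == "fragments") attr(bundle, "fragments") <- fragments
  bundle
}

#' Truth features as a GenomeFeatures set
#'
#' @param truth A `"SyntheticTruth"`.
#' @param what One of `"tfPeaks"`, `"rnapPeaks"`, `"epods"`.
#' @param condition Restrict TF peaks to those active in this condition
#'   (`NULL` = all).
#' @return A [GenomeFeatures-class].
#' @export
truthFeatures <- function(truth, what = c("tfPeaks", "rnapPeaks", "epods"),
                          condition = NULL) {
  what <- match.arg(what)
  f <- truth[[what]]
  if (!is.null(condition) && nrow(f) > 0) {
    act <- vapply(f$conditions, function(cs) {
      cs == "all" || condition %in% strsplit(cs, ";", fixed = TRUE)[[1]]
    }, logical(1))
    f <- f[act, , drop = FALSE]
  }
  GenomeFeatures(f$start, f$end, truth$genomeLength, score = f$amplitude,
                 name = sprintf("%s_%d", what, seq_len(max(nrow(f), 0))),
                 source = "truth", chrom = "synthetic")
}

#' Write the planted truth to disk
#'
#' Feature classes as GFF3 plus a JSON of the scalar parameters.
#'
#' @param truth A `"SyntheticTruth"`.
#' @param dir Output directory (created if needed).
#' @export
writeSyntheticTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in c("tfPeaks", "rnapPeaks", "epods")) {
    f <- truthFeatures(truth, w)
    if (length(f) > 0)
      writeFeatures(f, file.path(dir, paste0("truth_", w, ".gff3")),
                    format = "gff3", type = w)
  }
  scalars <- truth[c("genomeLength", "resolution", "oriPosition",
                     "gradientFold", "couplingSlope", "noiseSigma",
                     "baseDepth")]
  jsonlite::write_json(scalars, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Interval-level recall, precision, and Jaccard of calls against truth
#'
#' A truth interval is recovered when some called interval matches it with
#' reciprocal overlap at least `minReciprocal` (overlap length relative to
#' each interval's length); precision applies the same criterion to the
#' called intervals. Jaccard is computed at base-pair level on the union
#' masks.
#'
#' @param truth,called [GenomeFeatures-class] sets on the same genome.
#' @param minReciprocal Reciprocal-overlap match criterion (default 0.5).
#' @return List with `recall`, `precision`, `jaccard`; with no calls,
#'   precision is `NA` and flagged by attribute `"empty"`.
#' @export
truthVsCalled <- function(truth, called, minReciprocal = 0.5) {
  L <- truth@genomeLength
  nt <- length(truth); nc <- length(called)
  if (nc == 0) {
    out <- list(recall = 0, precision = NA_real_, jaccard = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  ovl <- function(s1, e1, s2, e2) {
    # base-pair overlap of two possibly wrapping intervals
    arms <- function(s, e) if (e > s) list(c(s, e)) else list(c(s, L), c(0, e))
    tot <- 0
    for (a in arms(s1, e1)) for (b in arms(s2, e2))
      tot <- tot + max(0, min(a[2], b[2]) - max(a[1], b[1]))
    tot
  }
  lenT <- featureLengths(truth); lenC <- featureLengths(called)
  matchT <- logical(nt); matchC <- logical(nc)
  for (i in seq_len(nt)) for (j in seq_len(nc)) {
    o <- ovl(truth@start[i], truth@end[i], called@start[j], called@end[j])
    if (o / lenT[i] >= minReciprocal && o / lenC[j] >= minReciprocal) {
      matchT[i] <- TRUE; matchC[j] <- TRUE
    }
  }
  mt <- featureMask(truth, L); mc <- featureMask(called, L)
  list(recall = if (nt > 0) mean(matchT) else NA_real_,
       precision = mean(matchC),
       jaccard = sum(mt & mc) / sum(mt | mc))
}
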