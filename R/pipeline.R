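#' Read a pipeline run configuration
#'
#' YAML with a `conditions` map (per condition: `input`/`ipod`/`chip` lists
#' of bedGraph or fragment-BED paths), `genomeLength`, and optional
#' `parameters` overriding any pipeline default (resolution, nKnots,
#' pseudocount, topFrac, coverFrac, widthsBp, snrThresholds, padBp,
#' kPercentiles, seed, ...). Every referenced file must exist and every seed
#' is explicit.
#'
#' @param path YAML file.
#' @return A validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$conditions) || is.null(cfg$genomeLength))
    stop("config must define 'conditions' and 'genomeLength'")
  for (cn in names(cfg$conditions)) {
    cc <- cfg$conditions[[cn]]
    for (type in c("input", "ipod", "chip")) {
      if (is.null(cc[[type]]) || length(cc[[type]]) < 1)
        stop("condition '", cn, "' lacks ", type, " replicates")
      missing <- !file.exists(unlist(cc[[type]]))
      if (any(missing))
        stop("condition '", cn, "': missing file(s): ",
             paste(unlist(cc[[type]])[missing], collapse = ", "))
    }
  }
  cfg$parameters <- utils::modifyList(defaultParameters(), cfg$parameters %||% list())
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline parameters
#'
#' All tunables of the processing chain with their standard values:
#' 5-bp bins; 4 spline knots; pseudocount 0; subtraction fit on the top 2%
#' of ChIP bins with 95% coverage; CWT widths 25-125 bp (step 5) with 30-bp
#' padding and thresholds 2,3,4,6,8,10 (threshold 4 as the analysis
#' default); EPOD percentiles 90 (strict) and 75 (relaxed); site floor 0.01
#' and detectability z > 3; 1000 bootstrap replicates; 100 K-means runs at
#' k = 8..12 cut at 10 clusters; 3x motif background and 20 decoys; 100-bp
#' TSS window.
#'
#' @return Named list of defaults.
#' @export
defaultParameters <- function() {
  list(resolution = 5, nKnots = 4, smoothing = NULL, pseudocount = 0,
       topFrac = 0.02, coverFrac = 0.95,
       widthsBp = seq(25, 125, by = 5), snrThresholds = c(2, 3, 4, 6, 8, 10),
       analysisThreshold = 4, padBp = 30,
       kStrict = 90, kRelaxed = 75,
       siteFloor = 0.01, detectZ = 3, nBoot = 1000,
       clusterRuns = 100, kRange = 8:12, nFinalClusters = 10,
       bgMultiple = 3, nDecoys = 20, tssWindowBp = 100,
       seed = 1)
}

.loadReplicates <- function(paths, genomeLength, resolution) {
  lapply(unlist(paths), function(p) {
    if (grepl("\\.bed$", p, ignore.case = TRUE)) {
      frags <- readFeatures(p, format = "bed", genomeLength = genomeLength)
      fragmentOccupancy(frags, resolution = resolution)
    } else {
      tr <- readTrack(p, genomeLength, resolution)
      tr@values[is.na(tr@values)] <- 0  # uncovered bins carry zero fragments
      tr
    }
  })
}

#' Run the per-condition workflow
#'
#' Executes quantify (when fragment BEDs are given), normalization, RNA
#' polymerase subtraction and scoring, CWT peak calling, and EPOD calling
#' for one condition, writing all tracks, feature GFFs, and a JSON run
#' report (slope, thresholds, counts, seeds) under `outDir`.
#'
#' @param config A config list from [readRunConfig()], or one built in code.
#' @param condition Condition name (must exist in the config).
#' @param outDir Output directory; `NULL` suppresses file output.
#' @param bundle Optionally, a pre-built [ConditionBundle-class] (bypasses
#'   the file manifests).
#' @return List with `profile` ([ScoredProfile-class]), `peaks` (scored
#'   data.frame), `epodsStrict`, `epodsRelaxed`, `bundle`, `report`.
#' @export
runCondition <- function(config, condition, outDir = NULL, bundle = NULL) {
  p <- config$parameters %||% defaultParameters()
  if (is.null(bundle)) {
    cc <- config$conditions[[condition]]
    if (is.null(cc)) stop("unknown condition '", condition, "'")
    stage <- "quantify"
    bundle <- tryCatch(
      ConditionBundle(
        .loadReplicates(cc$input, config$genomeLength, p$resolution),
        .loadReplicates(cc$ipod, config$genomeLength, p$resolution),
        .loadReplicates(cc$chip, config$genomeLength, p$resolution),
        condition = condition),
      error = function(e) stop("[", stage, "] ", conditionMessage(e)))
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) stop("[", stage, "] ", conditionMessage(e)))
  }
  bundle <- runStage("normalize",
    normalizeCondition(bundle, nKnots = p$nKnots, smoothing = p$smoothing,
                       pseudocount = p$pseudocount))
  profile <- runStage("chipsub",
    scoreCondition(bundle, topFrac = p$topFrac, coverFrac = p$coverFrac))
  peaks <- runStage("peaks", {
    pk <- callPeaksCwt(profile@robustZ, widthsBp = p$widthsBp,
                       snrThresholds = p$snrThresholds, padBp = p$padBp)
    scorePeaks(pk, profile@robustZ)
  })
  epodsStrict <- runStage("epods",
    callEpods(profile@robustZ, epodParams(kPercentile = p$kStrict)))
  epodsRelaxed <- runStage("epods",
    callEpods(profile@robustZ, epodParams(kPercentile = p$kRelaxed)))
  report <- list(
    condition = condition,
    seed = p$seed,
    slope = profile@model@slope,
    nFitPoints = profile@model@nFitPoints,
    nPeaks = nrow(peaks),
    nPeaksAtAnalysisThreshold = sum(peaks$snr >= p$analysisThreshold),
    epodThresholdStrict = attr(epodsStrict, "threshold"),
    epodThresholdRelaxed = attr(epodsRelaxed, "threshold"),
    nEpodsStrict = length(epodsStrict),
    nEpodsRelaxed = length(epodsRelaxed),
    parameters = p[c("resolution", "nKnots", "pseudocount", "topFrac",
                     "coverFrac", "padBp", "kStrict", "kRelaxed")])
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    d <- bundle@derived
    writeTrack(d$ipodLog2, file.path(outDir, "ipod_log2.bedgraph"))
    writeTrack(d$chipLog2, file.path(outDir, "chip_log2.bedgraph"))
    writeTrack(profile@chipsub, file.path(outDir, "chipsub.bedgraph"))
    writeTrack(profile@robustZ, file.path(outDir, "robust_z.bedgraph"))
    writeTrack(profile@neglog10p, file.path(outDir, "neglog10p.bedgraph"))
    pkAt <- peaksAtThreshold(peaks, p$analysisThreshold, config$genomeLength)
    writeFeatures(peaksToFeatures(pkAt, config$genomeLength),
                  file.path(outDir, "peaks.gff3"), format = "gff3",
                  type = "protein_occupancy_peak")
    if (length(epodsStrict) > 0)
      writeFeatures(epodsStrict, file.path(outDir, "epods_strict.gff3"),
                    format = "gff3", type = "EPOD")
    if (length(epodsRelaxed) > 0)
      writeFeatures(epodsRelaxed, file.path(outDir, "epods_relaxed.gff3"),
                    format = "gff3", type = "EPOD")
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(profile = profile, peaks = peaks, epodsStrict = epodsStrict,
       epodsRelaxed = epodsRelaxed, bundle = bundle, report = report)
}

#' Run the multi-condition analyses
#'
#' Scores every condition with [runCondition()], then computes the
#' cross-condition results: TF occupancy matrix and consensus clustering
#' (when a binding-site set is supplied) and the pairwise EPOD overlap and
#' relaxed-containment matrices.
#'
#' @param config Config list.
#' @param conditions Condition names (default: all in the config).
#' @param sites Optional [GenomeFeatures-class] of TF binding sites
#'   (`name` = TF).
#' @param outDir Optional output directory.
#' @param bundles Optional named list of pre-built bundles.
#' @return List with `perCondition`, `epodOverlap`, `epodContainment`, and
#'   (with sites) `tfMatrix`, `clustering`.
#' @export
runMulti <- function(config, conditions = NULL, sites = NULL, outDir = NULL,
                     bundles = NULL) {
  p <- config$parameters %||% defaultParameters()
  if (is.null(conditions)) conditions <- names(config$conditions) %||% names(bundles)
  if (length(conditions) < 2) stop("need at least 2 conditions")
  per <- lapply(conditions, function(cn) {
    runCondition(config, cn,
                 outDir = if (is.null(outDir)) NULL else file.path(outDir, cn),
                 bundle = bundles[[cn]])
  })
  names(per) <- conditions
  strict <- lapply(per, `[[`, "epodsStrict")
  relaxed <- lapply(per, `[[`, "epodsRelaxed")
  ov <- epodOverlapMatrix(strict, config$genomeLength)
  cont <- matrix(NA_real_, length(conditions), length(conditions),
                 dimnames = list(conditions, conditions))
  for (a in conditions) for (b in conditions)
    cont[a, b] <- as.numeric(epodContainment(strict[[a]], relaxed[[b]],
                                             config$genomeLength))
  out <- list(perCondition = per, epodOverlap = ov, epodContainment = cont)
  if (!is.null(sites)) {
    tables <- lapply(per, function(r) siteOccupancy(r$profile, sites, p$detectZ))
    out$tfMatrix <- tfConditionScore(tables, floor = p$siteFloor)
    nf <- min(p$nFinalClusters, nrow(out$tfMatrix@scores))
    out$clustering <- consensusCluster(out$tfMatrix, nRuns = p$clusterRuns,
                                       kRange = p$kRange, nFinal = nf,
                                       seed = p$seed)
    if (!is.null(outDir)) {
      utils::write.table(out$tfMatrix@scores,
                         file.path(outDir, "tf_occupancy.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(out$clustering@kappa,
                         file.path(outDir, "kappa.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }
  out
}
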