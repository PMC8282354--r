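# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (explicit loops, per-bp accumulation, direct scans) so
# they share no code path with the package implementations they check.

zTrack <- function(values, resolution = 5, circular = TRUE) {
  GenomeTrack(values, genomeLength = length(values) * resolution,
              resolution = resolution, circular = circular)
}

plantGaussian <- function(values, centerBin, sdBins, amplitude) {
  i <- seq_along(values)
  d <- abs(i - centerBin)
  d <- pmin(d, length(values) - d)
  values + amplitude * exp(-d^2 / (2 * sdBins^2))
}

# naive centered circular rolling mean, NA-aware
naiveRollingMean <- function(x, wBins, circular = TRUE) {
  n <- length(x)
  if (wBins %% 2 == 0) wBins <- wBins + 1
  h <- (wBins - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - h):(i + h)
    if (circular) idx <- (idx - 1) %% n + 1
    else idx <- idx[idx >= 1 & idx <= n]
    v <- x[idx]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

# per-bp brute-force fragment accumulation
bruteFragmentOccupancy <- function(start, end, L, res) {
  perbp <- numeric(L)
  for (k in seq_along(start)) {
    s <- start[k]; e <- end[k]
    bps <- if (e > s) (s + 1):e else c((s + 1):L, seq_len(e))
    w <- 1 / length(bps)
    for (b in bps) perbp[b] <- perbp[b] + w
  }
  n <- ceiling(L / res)
  out <- numeric(n)
  for (b in seq_len(L)) {
    bin <- floor((b - 1) / res) + 1
    out[bin] <- out[bin] + perbp[b]
  }
  out
}

# minimal slope by direct scan on a 1e-4 grid: smallest non-negative slope
# keeping at least ceil(coverFrac * n) ratios non-above
bruteForceSlope <- function(ratios, coverFrac, gridStep = 1e-4) {
  need <- ceiling(coverFrac * length(ratios))
  grid <- seq(0, max(ratios, 0) + gridStep, by = gridStep)
  for (s in grid) {
    if (sum(ratios <= s + 1e-12) >= need) return(s)
  }
  stop("no slope found")
}

# naive EPOD caller: direct reimplementation of the seed-and-extend rules
# with per-step mean recomputation
naiveEpods <- function(zv, res, k, seedWindowBp = 512, thresholdWindowBp = 256,
                       minSeedBp = 1024, floorZ = 0) {
  n <- length(zv)
  r256 <- naiveRollingMean(zv, round(thresholdWindowBp / res))
  Tthr <- as.numeric(stats::quantile(r256, k / 100, na.rm = TRUE, type = 7))
  r512 <- naiveRollingMean(zv, round(seedWindowBp / res))
  above <- !is.na(r512) & r512 > Tthr
  # circular runs by direct scan
  runs <- list()
  if (any(above) && !all(above)) {
    i <- which(!above)[1]
    ordered <- ((i:(i + n - 1)) - 1) %% n + 1
    cur <- NULL
    for (j in ordered) {
      if (above[j]) {
        if (is.null(cur)) cur <- c(j, j) else cur[2] <- j
      } else if (!is.null(cur)) { runs[[length(runs) + 1]] <- cur; cur <- NULL }
    }
    if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  } else if (all(above)) runs <- list(c(1, n))
  minBins <- ceiling(minSeedBp / res)
  runLen <- function(r) if (r[2] >= r[1]) r[2] - r[1] + 1 else n - r[1] + 1 + r[2]
  runBins <- function(r) if (r[2] >= r[1]) r[1]:r[2] else c(r[1]:n, 1:r[2])
  runs <- Filter(function(r) runLen(r) >= minBins, runs)
  if (length(runs) == 0) return(NULL)
  means <- vapply(runs, function(r) mean(zv[runBins(r)], na.rm = TRUE), numeric(1))
  runs <- runs[order(means, decreasing = TRUE)]
  claimed <- rep(FALSE, n)
  calls <- list()
  for (r in runs) {
    bins <- runBins(r)
    if (any(claimed[bins])) next
    lo <- r[1]; hi <- r[2]
    repeat {
      cur <- if (hi >= lo) lo:hi else c(lo:n, 1:hi)
      if (length(cur) >= n) break
      bl <- if (lo == 1) n else lo - 1
      br <- if (hi == n) 1 else hi + 1
      okL <- !claimed[bl] && !is.na(zv[bl]) && zv[bl] > floorZ
      okR <- !claimed[br] && !is.na(zv[br]) && zv[br] > floorZ
      if (!okL && !okR) break
      order_sides <- if (okL && (!okR || zv[bl] >= zv[br])) c("L", "R") else c("R", "L")
      grew <- FALSE
      for (sd in order_sides) {
        if (sd == "L" && okL && mean(zv[c(bl, cur)], na.rm = TRUE) > Tthr) {
          lo <- bl; grew <- TRUE; break
        }
        if (sd == "R" && okR && mean(zv[c(cur, br)], na.rm = TRUE) > Tthr) {
          hi <- br; grew <- TRUE; break
        }
      }
      if (!grew) break
    }
    bins <- if (hi >= lo) lo:hi else c(lo:n, 1:hi)
    claimed[bins] <- TRUE
    calls[[length(calls) + 1]] <-
      c(start = (lo - 1) * res, end = hi * res, meanZ = mean(zv[bins], na.rm = TRUE))
  }
  df <- as.data.frame(do.call(rbind, calls))
  df[order(df$start), , drop = FALSE]
}

# deterministic 10-group TF profile matrix for clustering tests
plantedTfMatrix <- function(nGroups = 10, perGroup = 5, nCond = 6,
                            noiseSd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    # fixed well-separated prototypes: indicator patterns over conditions
    pat <- rbind(diag(nCond),
                 t(utils::combn(nCond, 2))[seq_len(nGroups - nCond), , drop = FALSE] |>
                   apply(1, function(p) { v <- numeric(nCond); v[p] <- 1; v }) |> t())
    proto <- 0.1 + 0.8 * pat[seq_len(nGroups), , drop = FALSE]
    mat <- proto[rep(seq_len(nGroups), each = perGroup), ] +
      matrix(rnorm(nGroups * perGroup * nCond, 0, noiseSd), nGroups * perGroup)
    rownames(mat) <- sprintf("TF%02d", seq_len(nGroups * perGroup))
    list(mat = mat, groups = rep(seq_len(nGroups), each = perGroup))
  })
}

# agreement of two partitions up to label permutation
samePartition <- function(a, b) {
  identical(unname(as.integer(factor(a, levels = unique(a)))),
            unname(as.integer(factor(b, levels = unique(b)))))
}
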