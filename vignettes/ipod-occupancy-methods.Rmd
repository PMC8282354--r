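---
title: "Protein occupancy profiling on circular bacterial chromosomes: methods and design"
author: "ipodr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein occupancy profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipodr)
```

# The measurement and the model

IPOD-HR (in vivo protein occupancy display, high resolution) profiles total
protein occupancy along a bacterial chromosome: crosslinked protein--DNA
complexes partition to the phenol--chloroform interphase, and sequencing the
recovered DNA yields an occupancy signal at every position. Three samples are
sequenced per biological condition: the **input** (sheared genomic DNA), the
**IPOD interphase** fraction, and an **RNA polymerase ChIP**. The central
modeling problem is that the interphase signal mixes two kinds of occupancy:
RNA polymerase itself, and everything else (transcription factors and
nucleoid-associated proteins). `ipodr` implements the full chain from
aligned fragments to an RNA-polymerase-corrected occupancy score, plus the
feature callers and cross-condition analyses built on that score.

Throughout, signal lives on a fixed 5-bp bin grid over a circular
chromosome (`GenomeTrack`); intervals are 0-based half-open and may wrap the
origin (`GenomeFeatures`). All rolling statistics wrap across the origin.

# Per-condition processing chain

`normalizeCondition()` runs, in order:

1. **Quantile normalization** (`quantileNormalize()`) across replicates,
   separately within each sample type of each condition, so replicate
   marginal distributions agree exactly.
2. **Copy-number correction** (`fitPeriodicSpline()`,
   `copyNumberCorrect()`). Ongoing replication makes DNA near the origin
   more abundant than near the terminus. A cyclic cubic smoothing spline
   with 4 evenly spaced knots (at the origin, terminus, and the midpoints;
   smoothing penalty chosen by generalized cross-validation via `mgcv`) is
   fitted to the replicate-averaged input and every track is divided by it.
   Four knots allow inflection points exactly where replication biology puts
   them. We fit to the averaged input rather than per replicate: the
   gradient is a property of the culture, not of library preparation.
3. **Mean matching** (`matchMeans()`) of all tracks to a common mean, then
   **replicate averaging** (`averageReplicates()`), then **log2
   extracted:input ratios** (`log2Ratio()`) giving the IPOD and ChIP
   signals. The default pseudocount is 0 because post-normalization values
   are strictly positive in practice; it is a parameter for degenerate
   inputs.

## RNA polymerase subtraction

In the (ChIP, IPOD) plane, positions bound only by RNA polymerase fall on a
line through the origin; positions with additional protein occupancy lie
above it. `fitSubtractionSlope()` uses only the top 2% of bins by ChIP
signal (presumed pure polymerase), and finds the line of lowest non-negative
slope with zero intercept that keeps 95% of those bins at or below it. With
positive ChIP values this is an order statistic of the per-bin ipod/chip
ratios -- the smallest ratio covering `ceiling(0.95 * n)` points -- computed
without interpolation, so the "lowest possible slope" phrasing is honored
exactly. `subtractRnap()` removes `slope * chip` wherever the observed ChIP
signal is positive; elsewhere no subtraction happens, so the correction can
only lower occupancy. The 95% coverage is deliberately conservative: it
removes essentially all polymerase-attributable signal at the cost of
erasing some real occupancy at heavily transcribed positions. `coverFrac`
is exposed for users who prefer a balance closer to an ordinary fit (~50%).

## Scoring

The corrected signal is standardized as robust z-scores,
`z = (x - median(X)) / mad(X)` with the *unscaled* median absolute
deviation (no 1.4826 consistency factor), and converted to one-sided
upper-tail p-values under a standard normal null, reported as -log10 p
(`robustZ()`, `neglog10Pvalues()`; the tail is computed in log space so
large z keep full precision). Uncertainty is summarized pessimistically:
`replicateExtremeInterval()` recomputes the whole scoring chain for every
combination of one IPOD, one ChIP, and one input replicate and returns the
per-bin extremes. We compute the interval on the final -log10 p scale (the
scale on which site-level occupancies and their error bars are reported);
the point estimate is not mathematically guaranteed to lie inside because
replicate averaging enters nonlinearly, so only `lo <= hi` is asserted.

# Feature calling

## Binding-site-scale peaks

`callPeaksCwt()` implements ridge-line continuous-wavelet-transform peak
detection with a Mexican-hat wavelet over widths 25--125 bp in 5-bp steps
(the expected footprint range given input fragmentation). Per-scale local
maxima are linked across the width ladder (positional tolerance width/4,
gap tolerance 2 scales); ridges spanning at least a quarter of the ladder
are kept. The signal-to-noise ratio divides the ridge's maximum
coefficient -- its response at the matched scale -- by the magnitude of the
signed 10th percentile of the smallest-width coefficients in a centered
1000-bin window. For zero-mean noise that percentile sits near -1.3 times
the local coefficient scale, making the default thresholds (2--10, with 4
as the analysis default) meaningful: on unit-noise tracks no spurious peak
reaches threshold 4, while planted bumps of amplitude 8 z-units and widths
50--150 bp are recovered with recall and precision 1.0 in the test suite.
Using the matched-scale response rather than the smallest-scale coefficient
is a deliberate choice: the smallest-scale variant systematically
under-scores wide (>100 bp) footprints. Each call is padded by 30 bp per
side; peak sets at different thresholds are nested by construction, and a
peak's score is the most stringent threshold its SNR passes. Overlapping
padded calls within a threshold set merge, keeping the minimum label.

## Extended protein occupancy domains

`callEpods()` detects kilobase-scale occupancy: the threshold `T` is the
k-th percentile (k = 90 strict, 75 relaxed; linear interpolation) of the
256-bp rolling mean of the robust-z track; seeds are maximal runs of at
least 1,024 bp where the 512-bp rolling mean exceeds `T`; overlapping seeds
keep the highest mean; seeds then grow bin by bin in both directions --
trying the side with the larger next value first, ties to the left -- while
the whole-call mean stays above `T`, never crossing a bin with z at or
below 0 (missing bins block). Extension also never enters bins claimed by a
previously emitted, higher-mean call, so calls never overlap; abutting
calls stay separate. Rolling windows are centered with an odd bin count
(the window in bins is `round(bp/resolution)`, plus one if even) -- the
centered-odd choice keeps the operator symmetric; whether windows are
centered or trailing is an open convention and this one is fixed here.
The threshold percentile is computed once, up front, not recomputed after
seed resolution.

One behavior of the mean-based rule deserves note: around a strong plateau
the 512-bp rolling mean spills over by up to half a window on each side, so
on an otherwise quiet chromosome a sub-1,024-bp plateau can still seed a
call. On a chromosome carrying a realistic (~10%) load of occupancy
domains, `T` sits at domain amplitude and the spill-over is clipped, so
sub-minimum plateaus are rejected; the tests exercise exactly that
construction. (The original domain definition used a rolling median, which
does not spill; the mean-based rule is the one implemented here.)

Set comparisons: `epodOverlapMatrix()` (symmetrized base-pair overlap),
`epodContainment()` (strict-in-relaxed fraction), and
`epodFeatureEnrichment()` (difference of medians of a 500-bp-smoothed
feature track inside vs outside domains, tested against 1,000 random
circular rotations of the domain coordinates). All permutation nulls in the
package are rigid rotations around the circular genome, which preserve the
autocorrelation of both data and features, with the add-one p-value
estimator so p is never 0.

# Condition-resolved TF occupancy

`siteOccupancy()` merges overlapping or bookended sites of the same factor,
summarizes each site by its maximum -log10 p (the peak of the binding
signal), and flags sites detectable when the maximum robust z exceeds 3.
`tfConditionScore()` aggregates each factor's detectable sites per
condition by the geometric mean, flooring site values at 0.01 so a single
unbound site cannot zero the aggregate, and row-normalizes by each
factor's best condition onto (0, 1].

`consensusCluster()` clusters the normalized profiles 100 times with
randomly initialized K-means at each k in 8..12 and defines the
co-clustering frequency kappa(i, j) as the fraction of all 500 runs
pooled across k in which i and j share a cluster (pooling across k is a
design choice; per-k averaging gives the same ordering in practice).
`1 - kappa` feeds a final agglomerative clustering cut at 10 clusters.
Average linkage is used (the common choice on consensus matrices) and is
configurable. The whole procedure is bit-reproducible under a master seed.

`bootstrapSiteCi()` turns the pessimistic replicate ranges into confidence
intervals: each site's occupancy is resampled from a log-normal whose
arithmetic mean equals the observed value and whose arithmetic standard
deviation is one quarter of the replicate-extreme range (so the range acts
as a ~95% interval); 1,000 bootstrap replicates of the TF-level geometric
mean give the 2.5/97.5 band. Moment matching is done on the arithmetic
scale (`sigma^2 = log(1 + s^2/m^2)`); a normal-on-log-scale alternative is
available behind `logScaleNormal = TRUE`.

# Motif-discovery preparation

`buildFireDataset()` exports scored peak sequences (discrete score =
floor of the mean robust z over the raw call; negative-score peaks are
dropped from exports only) plus a background of unbound sequences: three
per peak, matching the peak length multiset exactly, rejection-sampled
(up to 10,000 attempts) from the genome outside all peaks. `makeDecoys()`
builds 20 circular-permutation decoys -- the peak coordinates rigidly
rotated by a uniform random offset -- preserving counts, lengths, scores,
and inter-peak spacing, and `motifFdr()` reports
`max(decoy counts) / max(real count, 1)`. `assignRegulons()` links motif
hits to transcriptional units whose annotated start site lies within 100
bp (inclusive, circular distance from the nearest edge of the hit; the
edge rather than the midpoint is used). External discovery and scanning
tools are consumed, not reimplemented.

# The synthetic generator

`generateCondition()` emulates the statistical structure the pipeline
assumes: a smooth copy-number gradient shaped as the exponential of a
cosine of angular distance from the origin (so a 4-knot periodic spline
can represent it), scaled so the ori:ter ratio equals `gradientFold`
(default 2, a typical fast-growth value); Gaussian RNA polymerase peaks
present in both ChIP and interphase tracks, coupled by `couplingSlope`
(default 1.2); Gaussian TF peaks and boxcar kilobase plateaus present only
in the interphase track; and independent per-bin log-normal replicate
noise. The default noise (`sdlog = 0.01`) and two replicates per sample
type represent deeply sequenced libraries where per-5-bp-bin sampling
noise is about 1%; the noise level is a parameter for stress tests. The
default desk-scale genome is 500 kb (tests mostly use 100 kb, i.e. 20,000
bins, so the full chain runs in seconds); an E. coli-scale 4.64-Mb preset
exists in the CLI. Fragment-level output draws per-bin Poisson counts with
intensity proportional to the track and fragment lengths uniform on
50--200 bp.

What the generator does *not* emulate: autocorrelated noise, GC or
mappability bias, sequence-dependent fragmentation, or multi-factor
competition at shared sites. Passing tests on synthetic data therefore
demonstrates correctness of the algorithms under the stated statistical
model, not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* Percentiles use R's default linear interpolation (type 7); the
  subtraction slope deliberately does not interpolate (order statistic).
* The robust-z step errors on zero MAD; the spline fit errors if more than
  1% of fitted values need the positivity floor; the slope fit requires at
  least 20 positive-ChIP bins in the top set.
* Missing bins propagate: they are excluded from rolling means and
  replicate averages, block EPOD extension, and are set to zero signal
  before the CWT (the robust-z track normally has none).
* K-means center counts are capped at the number of distinct profiles
  (minus one relative to the row count, as required by `stats::kmeans`).
* All randomized procedures (rotation tests, background sampling, decoys,
  bootstrap, clustering) take explicit seeds and are bit-reproducible.

# Worked example

```{r example, eval = FALSE}
truth <- randomSyntheticTruth(genomeLength = 1e5, seed = 7)
bundle <- normalizeCondition(generateCondition(truth, seed = 8))
profile <- scoreCondition(bundle)
profile@model          # fitted subtraction slope
peaks <- scorePeaks(callPeaksCwt(profile@robustZ), profile@robustZ)
epods <- callEpods(profile@robustZ, epodParams(kPercentile = 90))
truthVsCalled(truthFeatures(truth, "epods"), epods)
```

# Known limitations

* Single-chromosome genomes only; fragments arrive as BED intervals (BAM
  parsing is upstream).
* The replicate-extreme interval is exponential in replicate count (capped,
  default 64 combinations).
* The EPOD extension tie-break (left preference) and the non-merging of
  abutting calls are conventions; alternatives would shift boundaries by a
  few bins.
* The empirical decoy FDR is only as granular as `1 / real count`.
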