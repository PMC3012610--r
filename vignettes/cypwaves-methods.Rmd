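---
title: "Methods: the zebrafish CYP complement and its expression waves"
author: "cypwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the zebrafish CYP complement and its expression waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypwaves)
```

# Scope

Zebrafish carry 94 cytochrome P450 (CYP) genes in 18 families, many of
them in tandemly duplicated arrays, and most of them are expressed in
the embryo in successive "waves" between 3 and 48 hours
post-fertilization (hpf). `cypwaves` packages the genomic registry of
that complement together with the complete single-color microarray
analysis chain used to expose those waves — rank-invariant
normalization, probe quality control, an empirical-Bayes temporal
differential-expression score, and wave clustering — plus absolute qPCR
quantification against plasmid standard curves. Because the real
hybridizations are an external download, a fully seeded simulator
reproduces the study design with known ground truth, and every
downstream stage is tested against that truth.

# The gene registry

The packaged table (`cypRegistryFile()`) has one row per genomic locus:
96 rows, of which two genes (CYP2X10 and CYP2X12) appear twice as exact
assembly copies (`c1`/`c2` suffixes, flagged `assembly_duplicate`) and
two loci (CYP46A5, CYP2AA13) are supported by transcript evidence but
absent from the assembly (`missing_from_assembly`, no coordinates).
Counting follows one convention throughout: **a gene is a distinct base
name**, so assembly copies collapse and assembly-missing genes still
count. That yields 94 genes in 18 families. Eighty-eight genes carry
the `on_array` flag; the six without it are absent from the microarray,
which was designed against an earlier genome assembly.

Two published figures cannot be reconciled with any single counting
convention over the printed rows (47 CYP2 genes, and 32 genes in
families 5–51); the registry does not force them, and the counting
operations simply report what the convention above gives (46 and 34).

## Tandem clusters

`tandemClusters()` groups genes by single linkage along a chromosome
within one family: sort by transcript start (ties by end, then name)
and break whenever the gap to the running maximum end exceeds
`maxGap`. The default `maxGap = 100000` (100 kb) was chosen once, from
the printed coordinates: every intra-array gap in the known arrays is
under ~25 kb, while the CYP2AE pair sits roughly 230 kb downstream of
the CYP2AA array and must not merge with it. With that default the
registry yields the 8-gene CYP2K array on chromosome 3 (plus a separate
3-gene CYP2K group ~1.7 Mb away), the 10-gene CYP2AA array on
chromosome 23, and the 11-gene CYP2J-like cluster (CYP2N13, three
CYP2ADs, CYP2V1, six CYP2Ps) on chromosome 20. Coordinates are stored
1-based inclusive as annotated; only the BED exporter converts
(0-based, half-open).

# The simulator

`simulateTimecourse()` emulates the embryo study design: six sampling
times (3, 6, 12, 24, 36, 48 hpf), four independently maintained dishes
as biological replicates, every probe printed in duplicate. Signals
are built in log2 space:

* per-probe baseline ~ Normal(8, 2) log2 units — a realistic dynamic
  range for fluorescence intensities on a 16-bit scanner;
* an archetype effect: *maternal decay* (linear, default −0.15 log2/h
  from 3 hpf, i.e. ~10-fold loss over the series), *unimodal wave*
  (Gaussian bump, amplitude uniform on 1–3.5 log2, width 6 h),
  *bimodal* (bumps at 3 and 48 hpf), *flat*, or *below background*;
* replicate noise Normal(0, 0.25) per probe × array and spot noise
  Normal(0, 0.10) per spot — normal in log2, i.e. multiplicative on
  the linear scale, the standard intensity error structure and the
  reason the pipeline normalizes in log space;
* a per-array monotone affine distortion `y = a + b·x` with slope
  `b ~ U(0.8, 1.25)`, anchored so typical intensities stay centered —
  the systematic between-array effect the normalization must remove;
* conversion to linear scale, clipping at 65535 with a saturation
  flag; below-background probes are drawn on the linear scale from
  Normal(4, 1) truncated at zero and flagged not-above-background.

The default archetype mixture (15% maternal, 40% unimodal, 10%
bimodal, 30% flat, 5% below background) reflects an embryonic
transcriptome in which most expressed probes change over development.
Everything is drawn under one user-supplied seed, and the caller's RNG
state is restored afterwards, so identical seeds give byte-identical
data.

What the simulator does **not** emulate: spatial array artifacts, dye
chemistry, scanner background estimation (flags are planted, not
derived), probe-sequence effects, and the correlation structure of a
real transcriptome. Passing recovery tests therefore demonstrates that
the algorithms invert the generative model they were designed for, not
that they are optimal on any particular real dataset.

`simulateQcProfile()` is a separate planted fixture for the probe
filter's worked example: at the production scale of 21893 probes it
plants exactly 10 any-instance-saturated and 82 never-above-background
probes, so the filter must retain exactly 21801. Planting (rather than
waiting for organic clipping) is what makes the expected counts exact.

# Signal conditioning

The chain mirrors the single-color analysis convention:

1. **Floor** — linear values below 5 are set to 5 before
   normalization, keeping the log transform defined near background.
2. **Baseline selection** — the array whose median signal is the
   median of all per-array medians (lower median for even counts,
   lowest column index on residual ties).
3. **Rank-invariant probes** — iteratively retain features whose rank
   difference between target and baseline array is at most
   `thresholdFraction` (default 0.02) of the current set size. The
   exact constants of the original software are unpublished, so both
   are exposed as configuration. One stabilizer was added after
   analysis of the iteration's behavior: at realistic replicate noise
   the pure rank-band iteration contracts geometrically to the empty
   set, because re-ranking within the surviving subset leaves the
   *relative* rank jitter unchanged. The iteration therefore stops
   rather than shrink below `minSize` features (default 5% of the
   universe, at least 50), returning the last admissible set — the
   most rank-stable features, which is precisely what the curve fit
   needs. `minSize = 1` runs the unguarded scheme.
4. **Curve fit** — control points are the sorted invariant target
   values against a centered running median (`stats::runmed`, default
   window `min(101, n/10)` rounded odd — wide enough to be smooth,
   narrow enough to stay locally adaptive) of the baseline values,
   made monotone by a cumulative maximum; evaluation interpolates
   linearly and extends linearly beyond the range with the terminal
   segment slopes. Saturated instances are excluded from fitting but
   kept for flag propagation.
5. **Duplicate averaging** — arithmetic mean over a probe's spots on
   the normalized linear scale; flags aggregate across *every*
   instance (all arrays and spots).
6. **QC filter** — remove probes saturated in any instance, then
   probes above background in no instance. Saturation takes
   precedence, which makes the report's categories disjoint and its
   conservation identity (`retained = input − saturated − background`)
   hold on every input; the overlap handling is a package decision, as
   the convention for probes failing both criteria is not documented.

# Temporal differential expression

Standard per-timepoint ANOVA ignores the autocorrelation of a
developmental series, so the primary score is an empirical-Bayes
posterior in the spirit of Bayesian estimation of temporal regulation.
After log2 transform and per-probe median-centering, each probe is
summarized by the vector **d** of timepoint-mean differences relative
to the first timepoint (3 hpf). The model is a two-component
multivariate-normal mixture:

* **null**: `d ~ N(0, Σ0)` where `Σ0 = (s²/n)(I + 11ᵀ)` is the exact
  covariance of shared-reference mean differences, with the per-probe
  residual variance `s²` moderated by shrinking 10% of the way
  (`lambda = 0.1`) toward the pooled mean — enough to tame unstable
  per-probe variance estimates at n = 4 without flattening real
  differences;
* **alternative**: `d ~ N(0, Σ0 + Σ1)` with `Σ1` a free positive
  semi-definite signal covariance shared across probes, estimated by
  EM together with the mixture weight (tolerance 1e-6, at most 200
  iterations; `Σ1` is projected back to the PSD cone each step). Since
  the null covariances differ between probes only by the scalar `s²`,
  whitening by `(I + 11ᵀ)^{-1/2}` lets one eigendecomposition per EM
  step serve all probes.

The reported posterior is each probe's membership probability of the
alternative. The published significance criterion "p < 0.01" is read
on this scale as `1 − posterior < 0.01`; no multiple-testing
correction is applied by default (matching the raw threshold), with
Benjamini–Hochberg available through `temporalDE(adjust = "BH")`.
Probes with zero residual variance have no defined probability and
return `NA`. The naive one-way ANOVA (`stats::oneway.test`,
equal-variance) is computed alongside as the comparator; on mixed
simulations the two call sets overlap with Jaccard well above 0.8.

# Clustering the waves

Clustering operates on per-gene timepoint means (n = 4 replicates),
z-normalized within gene (population SD; constant rows become zero and
are flagged degenerate) so temporal shape rather than absolute level
drives the grouping. Gene-level means are used rather than probe-level
values — the natural unit for a per-gene heat map.

* **Hierarchical K-means** (`kmeansClusters`, default K = 10): the
  "hierarchical K-means" of the MeV tradition is read as
  hierarchically *initialized* K-means — average-linkage clustering on
  correlation distance cut at K seeds the centroids, then standard
  K-means refines. The initialization removes the usual random-restart
  nondeterminism.
* **CAST** (`castClusters`, affinity 0.7): pairwise affinity is
  `(Pearson r + 1)/2`, mapped to the 0–1 scale the threshold is quoted
  on (raw correlation available as an option). The greedy
  add/remove loop runs until stable; at termination every member's
  mean within-cluster affinity meets the threshold.
* **Affinity search** (`affinitySearch`): genes matching a seed
  profile at affinity ≥ 0.7. The default maternal seed is the
  z-normalized strictly decreasing ramp peaking at 3 hpf — the
  original seed profile is not distributed, so the canonical monotone
  decay stands in for it.
* **Modality** (`classifyModality`): local maxima above +0.5 z;
  maxima at both the first and last timepoints give `bimodal` (the
  pattern of elevated expression at both 3 and 48 hpf), a single
  first-timepoint maximum `peak_at_start`, otherwise `unimodal` with
  its peak time. The +0.5 z cutoff is a package decision; the
  published account names bimodal genes but states no rule.

# qPCR absolute quantification

`fitStandardCurve()` regresses Ct on log10(copies) over at least three
serial dilutions and reports amplification efficiency
`E = 10^(−1/slope) − 1`; `moleculeCount()` inverts the curve, flagging
Ct values outside the calibrated range as extrapolated rather than
refusing them (low-expressed CYPs near the detection limit routinely
fall below the last standard). Counts are normalized per sample to the
reference transcript ARNT2 — chosen because it varies far less across
development than beta-actin — and summarized as mean ± SD across
biological replicates (mean rather than median, matching how such data
are reported; a median mode is a one-line change).
`platformConcordance()` correlates reference-normalized array values
with reference-normalized molecule counts per gene; the concordance
call uses r ≥ 0.9 — the published criterion is qualitative
("linear relationships"), so the cutoff is configurable.

# Pipeline and determinism

`runPipeline()` chains simulate → floor → normalize → average
duplicates → filter → DE → cluster, writes `qc.json`, `de.tsv`,
`clusters.tsv`, and echoes every parameter (including every
under-specified constant above) plus the MD5 of each output into
`manifest.json`. No timestamps enter any output, so a rerun with the
same configuration and seed is byte-identical. A thin command-line
wrapper ships in `inst/scripts/cypwaves.R`.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant profiles get zero
z-scores and a flag, undefined correlations are treated as zero
(affinity 0.5, below every sensible threshold), zero-variance probes
get `NA` posteriors, and zero reference counts are an error rather
than an infinite ratio. Ties break deterministically everywhere
(lowest index / input order / gene name), so no result depends on hash
or iteration order.

The test suite exercises the production design at reduced probe counts
chosen as the package's own desk scale: 2000 probes for the
differential-expression operating characteristics (null call rate,
power, ANOVA concordance), 240 genes for clustering recovery, 600 for
normalization recovery, and the full 21893 probes for the QC worked
example. Recovery criteria: planted 2-log2 waves are detected with
posterior > 0.99 in ≥ 90% of cases; null call rates stay within three
times the nominal 0.01; both clustering methods reach adjusted Rand
index ≥ 0.95 against planted archetypes at zero noise and ≥ 0.7 at
replicate SD 0.25.

# Known limitations

The temporal-DE mixture shares one signal covariance across all
probes, so probes with unusual temporal correlation are scored against
an average signal model. The published software's exact rank-invariance
constants, CAST tie-breaking, and clustering input (probe- vs
gene-level) are not recoverable; the package fixes each by a
documented default. Normalizing strongly regulated transcriptomes
against a single baseline can leave small timepoint-systematic
residuals that inflate apparent regulation of flat probes; the
differential-expression operating characteristics quoted above are
measured on undistorted inputs, isolating the scorer from that
upstream effect. Counts that depend on the unresolved published
conventions (CYP2 totals) are reported under this package's convention
only.
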