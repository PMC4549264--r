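---
title: "Nucleosome architecture from mononucleosomal fragments: models and methods"
author: "nucarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome architecture methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nucarch` analyses nucleosome organization from MNase-seq mononucleosomal
fragment intervals: it builds per-base nucleosome occupancy score (NOS)
maps, calls nucleosomes under a minimum dyad spacing, measures
dyad-relative sequence composition and its periodicity by FFT, aggregates
occupancy around genomic features (TSSs, methylation sites, TFBSs),
clusters promoter architectures, relates DNA methylation to dyad geometry
with rank statistics, and scans for enhancer-like architectures
(a depleted region bounded by well-positioned nucleosomes).  A fully
parameterised synthetic-data generator with ground truth makes every stage
testable end to end without external data.

# The occupancy model

A sequenced mononucleosomal fragment protects the DNA wrapped around one
histone octamer, so its midpoint estimates the nucleosome dyad.  For a
fragment occupying the 0-based half-open interval `[start, end)` the
inferred dyad is `floor((start + end - 1) / 2)`; for even-length fragments
the midpoint rounds down (leftward), a convention applied everywhere.
Each dyad is extended to the canonical 147 bp core (dyad &plusmn; 73) and

> NOS(b) = number of dyad-centred cores covering base b.

This "nucleosome-size-adjusted coverage" needs no further smoothing: the
147 bp box is itself the smoother.  Two invariants pin the implementation
down exactly: the sum of the raw NOS equals 147 times the number of
accepted fragments (fragments whose core would stick out of the
chromosome are rejected, with a warning), and on noise-free synthetic
fragments the called dyads equal the true dyads exactly.

Tracks from different datasets are compared after linear scaling to a
common genome-wide mean of 100 (`normalizeTracks`); the scale is
arbitrary but fixed, and every statistic that matters is either a ratio or
scale-invariant.  Dataset concordance uses `binnedPCC`: masked bases are
dropped, the rest averaged in fixed 10 bp windows, and the Pearson
correlation computed over the concatenated bins.

# Nucleosome calling

`callNucleosomes` is a greedy summit caller.  Candidate summits are the
centres of maximal equal-value runs of the NOS track — an integer-valued
coverage signal is naturally plateau-shaped, and the centre of a tied
plateau is the only choice under which a noiseless single-nucleosome
plateau `[d - 73, d + 73]` calls its true dyad `d`.  Candidates are taken
highest-first (ties resolve to the leftmost run) and accepted unless they
fall within `minSpacing - 1` bp (default 150, matching the mean fragment
size of ~151 bp) of an already accepted dyad; selection stops below
`minSummit`.  Computing plateau centres *before* spacing exclusion
matters: excluding bases first would clip the plateau of a neighbouring
nucleosome and bias its called dyad by tens of bp.

Each call records its 147 bp core, summit NOS, core-mean NOS and a
*positioning score*: summit NOS divided by the mean NOS in a
&plusmn;500 bp window around the dyad excluding the core.  A flat track
scores 1; a zero background yields an `Inf` sentinel that ranks above all
finite scores.  The score is a ratio, so it is invariant under depth
normalization.

# Sequence periodicity

`dyadRelativeFrequency` tabulates mono- or dinucleotide frequencies at
each offset −73..+73 from a set of dyads (a dinucleotide is addressed by
its first base; at offset +73 it reads one base past the core edge, and
sites lacking that base are skipped for that offset only).
`fftPeriodogram` mean-subtracts the profile, zero-pads to 1024 points,
and takes the squared-magnitude spectrum.  The dominant period is
1/frequency at the in-band (default 2–20 bp) power maximum, refined by
quadratic interpolation around the peak bin.  Two guards make "no
periodicity" a computable verdict: the peak must exceed 4&times; the
median in-band power (configurable), and an in-band maximum sitting at a
band edge without being a local maximum of the full spectrum is rejected
— a smoothly decaying spectrum has no true peak.  With many in-band bins
the 4&times;-median rule alone is permissive (the max/median ratio of
pure noise grows with the number of bins), so verdicts on noisy profiles
should use a stricter ratio; the pure-profile detections (planted 8, 10
or 12 bp placement) exceed the default threshold by orders of magnitude.

`phasingPeriodogram` estimates the nucleosome repeat length (NRL):
sample windows (default 200 windows of 2 kb) from the NOS track, average
the autocorrelation of the mean-centred signal over lags up to 1 kb, and
Fourier-transform the mean autocorrelation, searching 120–300 bp.
Mean subtraction is the only detrending and no taper is applied: the
profiles are short, and zero-padding plus the interior-peak guard handle
the aperiodic edges.

# Metaprofiles, expression and clustering

Stranded RNA tracks are combined into a total RNA-Signal by scaling each
strand to the mean of the non-zero strand totals and adding per-base
values; a zero strand contributes nothing and does not rescale the other.
Gene expression is the *sum* of the combined signal over the gene span
(the sum, not the mean, so long lowly-covered genes are not inflated;
configurable).  Quartiles are assigned on ranks with stable tie-breaking.
A gene is silent iff its mean signal over the span &plusmn;500 bp is at
most `eps` (default 0 — truly no signal).

`profileMatrix`/`aggregateProfile` slice the track &plusmn;F around each
feature (default F = 1000 bp for TSS/TTS, 500 bp for point features),
reverse minus-strand rows so positive offsets point downstream in
transcription direction, and drop (and count) features too close to a
chromosome end.  For clustering, each row is divided by its own maximum
so that cluster structure reflects architecture rather than amplitude;
`kmeansProfiles` then runs Euclidean k-means (default k = 10, 10
restarts, fixed seed) and reports per-cluster centroid-maximum offsets.
The "+1 nucleosome" of an oriented mean profile is the first local
maximum in (0, 300] after 5 bp moving-average smoothing; shifts between
conditions are differences of these locations.

`activeSiteFilter` encodes "high accessibility, low occupancy" as
inclusive quantile thresholds over per-site means (defaults: accessibility
&ge; its 0.75 quantile AND NOS &le; its 0.25 quantile).  The quantiles are
explicit stand-ins for verbal thresholds; both are parameters.

`normalizeByReference` divides a per-gene profile by a reference profile
gene-by-gene with a pseudocount of 1 on the normalized scale, then
averages — the tool for quantifying how transcription deforms a
sequence-driven "ground state" measured in vitro.

# Methylation–dyad geometry

Sites are assigned to called cores by half-open interval membership; with
spacing &ge; 150 bp the cores cannot overlap, so assignment is unique.
Stratifying core-mean NOS by per-nucleosome site count (buckets 0, 1, 2,
3, 4+; the cap avoids sparse tails) uses a Kruskal–Wallis test followed
by all pairwise two-sided Mann–Whitney–Wilcoxon tests with Bonferroni
correction over the pairwise family (exact for small tie-free groups,
normal approximation otherwise).

`distanceToNearestDyad` reports the signed distance to the nearest dyad
(positive = downstream of the dyad; an equidistant site resolves to the
downstream dyad, giving the negative sign — the histograms are symmetric
so the choice is cosmetic, but it is fixed).  The core view spans
&plusmn;73 bp and is reported as percentages summing to 100.
`highOccupancySubset` repeats the mCG histogram using only sites inside
nucleosomes whose summit NOS strictly exceeds a threshold; `auto` sets
the threshold to the mean summit NOS of all called nucleosomes, the
dataset-specific analogue of a fixed published cutoff.  On ingest, mCG
records at positions that also carry an hmC record are dropped:
methylcytosine calls later shown to be hydroxymethylated are not mCG.

# Enhancer-architecture scan

`findPatterns` looks for a nucleosome-depleted region bounded by two
well-positioned nucleosomes inside a positioned neighbourhood: an
adjacent called pair with both positioning scores &ge; `posScoreMin`,
inter-dyad gap in `gapRange` (default 250–600 bp), trough NOS at most
`troughFracMax` (default 0.5) of the smaller summit, and at least
`minFlankSupport` (default 1) additional positioned nucleosomes within
`flankSearchBp` (default 450 bp) on each outer side.  Hits are emitted at
the trough midpoint with score `mean(pair scores) * (1 - trough /
min(summit))`, sorted by score, overlapping 200 bp windows deduplicated
keeping the best.  All thresholds are explicit parameters because the
pattern is only ever described verbally; `posScoreMin = 1.5` (a summit
1.5&times; enriched over its local background) was fixed by requiring
that the planted enhancer architectures in the default synthetic dataset
are recovered with recall &ge; 0.9 and precision &ge; 0.8 — the
calibration the scan configuration is documented to carry.  Every score
is a ratio, so hits are invariant under uniform scaling of the track.

# The synthetic-data generator

The generator emulates the features of real MNase-seq data that the
analyses consume, with known truth:

* **Genome and landscape** — 2 chromosomes &times; 1 Mb by default.
  Genes (200, fixed 3 kb bodies, unique TSSs, random strands) sit in
  evenly spaced territories.  Each gene draws one of 10 TSS architecture
  classes — (side, offset) of its major well-positioned promoter
  nucleosome, offsets 160–320 bp by 40 — and one of 4 expression tiers
  (relative rates 0, 1, 2, 4).  The promoter carries the major
  nucleosome, a fuzzy minor nucleosome on the opposite side at 160 bp,
  and a fuzzy "NDR filler" at the TSS whose weight decays with the tier
  (0.35 &times; 0.45^rank), so higher expression means an emptier NDR and
  a stronger +1 — the coupling behind the quartile-profile checks.
  Arrays continue at the 185 bp NRL through the gene body and
  intergenic space (70% positioned / 30% fuzzy); intergenic fills are
  respaced evenly so junction gaps stay in 170–250 bp, keeping spurious
  scan-range gaps out of the background.  Planted enhancer sites (24) are
  a 400 bp inter-dyad NDR bounded by weight-3 positioned nucleosomes with
  weight-2 positioned support at &plusmn;385 bp.  Bulk (array/intergenic)
  weights get a lognormal multiplier (sd 0.4 on the log scale) emulating
  the continuous occupancy range of real chromatin.  All dyads are kept
  &ge; 150 bp apart (heavier nucleosome wins a conflict).
* **Sequence** — linkers sample the background composition (GC 0.40);
  cores sample a GC-boosted background (+0.15) and additionally force
  AA/TT dinucleotide starts with per-offset probability
  `rate * (1 + A cos(2π p / P))` (rate 0.10, amplitude 0.6, period 10 bp),
  phase-locked to the dyad.  The motif forcing dilutes the GC boost, which
  is why the boost is 0.15 rather than a token 0.05: the *net* core GC
  enrichment after dilution is a few percent, as in real nucleosomal DNA.
* **Fragments** — 600,000 by default.  Each fragment picks a nucleosome
  proportionally to its occupancy weight; its midpoint is the dyad plus
  Gaussian jitter (σ = 10 bp positioned, 20 bp fuzzy), its length Normal
  (151 &plusmn; 15 bp) truncated to [100, 220] (mirroring mononucleosomal
  gel selection), and each record gains a PCR duplicate with probability
  0.1.  Two constraints fixed the depth and the fuzzy jitter once, at
  design time.  First, at a 185 bp repeat, fuzzy midpoint spread much
  beyond σ ≈ (NRL − 125)/3 ≈ 20 bp bleeds neighbouring midpoints into a
  positioned nucleosome's core window; a single stray count then tops the
  summit plateau and dyad attribution by midpoint counting becomes
  ill-posed for *any* argmax caller, so σ_fuzzy = 20 bp is the largest
  fuzzy spread under which per-nucleosome dyad recovery is a meaningful
  target.  Second, binned-track replicate concordance is
  depth-limited: the per-10 bp-bin noise is Poisson in the fragment count
  while the biological signal is fixed, and at 0.1 fragments/bp
  (200,000) the noise share keeps half-depth replicate correlations well
  below the 0.9 that pooled-replicate real datasets show; 0.3
  fragments/bp (600,000, i.e. deep pooled-replicate coverage) is the
  scale at which the generator reproduces that regime.
* **RNA and annotations** — tier &times; lognormal noise per-base signal
  on the gene strand (silent tier exactly zero); promoter histone marks
  (H3K4me3 top tier, H3K27me3 silent, both = bivalent), chromatin-state
  labels, and TFBS intervals at enhancers and active promoters.
* **Methylation** — per context (mCG/mCHG/mCHH/hmC), a per-bp density, a
  core fraction, and a dyad-relative placement density over −73..+73.
  Core sites pick a nucleosome proportionally to occupancy weight (the
  coupling that makes occupancy increase with methylation count) and an
  offset from the context's profile; mCG in high-occupancy nucleosomes
  (weight &ge; 2) is tilted toward the dyad.  The default mCG profile has
  modes at 0 and &plusmn;40 bp; mCHH places 80% of its sites uniformly in
  linkers.  Sites are coordinates without strand.  When a genome is
  supplied, placements are rejection-sampled onto C/G bases; by default
  placement is purely positional, which leaves the dyad-relative
  geometry identical.

What the generator does **not** emulate: raw reads and sequencing error,
mappability, MNase sequence bias, copy-number structure, linker
histones, or cell-to-cell heterogeneity.  Passing the parameter-recovery
suite therefore shows the *pipeline* is correct and calibrated on data
satisfying its assumptions — not that real chromatin satisfies them.

# Numerical choices and degenerate inputs

* Even-length fragment midpoints round down; documented and applied
  everywhere.
* Caller ties: plateau centre, leftmost plateau first.  An all-zero track
  calls nothing; `minSpacing` below 147 warns (cores may overlap).
* FFT: mean subtraction only; zero-pad to 1024 (8192 for phasing, whose
  band sits at much lower frequency); quadratic peak interpolation; a
  constant profile yields an empty spectrum and "no period".
* `normalizeTracks` refuses all-zero datasets; normalization is
  idempotent.
* `binnedPCC` errors on fewer than two usable bins or zero variance
  rather than returning NA.
* Pseudocounts: 1.0 on the normalized (mean-100) scale in
  `normalizeByReference`.
* All generator randomness derives from one seed through fixed per-stage
  substreams (landscape +0, sequence +1, fragments +2, annotations +3,
  methylation +4), so each stage is independently reproducible and the
  caller's RNG state is restored afterwards.

# Problem sizes

The shipped configuration — 2 Mb of genome, ~10,800 nucleosomes, 600,000
fragments, 200 genes, 24 enhancers, ~33,000 methylation sites — was
chosen so that spectral estimates and recovery rates are stable while the
full simulate–map–call–analyse cycle runs in well under a minute on a
single core; the test suite and the acceptance script regenerate
everything from scratch at this scale.

# Known limitations

* The caller reports fixed 147 bp cores; it does not estimate fragment-
  supported core edges, and overlapping alternative positioning within a
  cell population is summarised by a single dyad.
* Positioning scores depend on the local background window (500 bp); very
  long depleted regions inflate the scores of their bounding nucleosomes
  — which the scan exploits deliberately, but which makes the score a
  relative, not absolute, measure of positioning.
* The Mann–Whitney tests fall back to the normal approximation under
  ties, as usual for rank tests on large coverage-derived quantities.
* Periodicity verdicts on noisy profiles depend on the peak-significance
  rule; the default 4&times;-median threshold is calibrated for strong
  planted signals and should be raised for exploratory scans of weak
  ones.
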