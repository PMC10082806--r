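---
title: "nanodmr: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanodmr: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation model

`nanodmr` calls differentially methylated regions (DMRs) between two
long-read methylomes. The substrate is the per-CpG-group difference of
methylation frequencies, Δβ_i = β_test,i − β_control,i ∈ [−1, 1], at the
CpG groups covered in both samples. Δβ is modelled as a shifting-level
process

Δβ_i = m_i + ε_i,

with an unobserved piecewise-constant mean level m_i and truncated-Gaussian
white noise ε_i ~ N(0, σ_ε²) bounded to [−1, 1] (Δβ cannot leave that
range, so an unbounded Gaussian would put mass on impossible values and
bias likelihoods near the extremes). The level persists for geometric
durations; at a change point it moves by a Gaussian increment
δ ~ N(0, σ_μ²).

The model is *heterogeneous* because the level-change probability between
consecutive CpG groups depends on their genomic distance d (in bp):

η(d) = θ/2 + (1/2 − θ) · exp[ log(θ) / (d / d_Norm) ].

η is monotone non-decreasing in d, with limits θ/2 as d → 0⁺ and
(1 − θ)/2 as d → ∞, and η(d_Norm) = θ − θ². Intuitively: two CpGs 10 bp
apart almost surely share a methylation state, two CpGs 100 kb apart carry
almost independent states, and η interpolates between those regimes on the
scale set by d_Norm.

### Decoding

The continuous level m is discretised onto a symmetric grid of `nStates`
candidate levels on [−1, 1] (odd, so 0 is always on the grid), and the
maximum a posteriori level path is computed by the Viterbi algorithm
(`src/viterbi.cpp`):

* initial distribution: stationary weights w_k ∝ N(level_k; 0, σ_μ²);
* transition at step i: stay with probability 1 − η(d_i); jump from j to
  k ≠ j with probability η(d_i) · N(level_k − level_j; 0, σ_μ²),
  renormalised over k ≠ j (the jump-target law mirrors the Gaussian
  increment assumption; a stationary re-draw would not);
* emission: truncated Gaussian N(level_k, σ_ε²) on [−1, 1].

All arithmetic is in log space. Ties — which have probability zero for
continuous inputs but can arise on degenerate ones — are broken toward the
lower state index both in the per-step argmax and in the final state, so
decoding is deterministic. Chromosomes are segmented independently; tracks
never span chromosome boundaries, and no special handling of assembly gaps
is attempted (a large gap simply raises η toward its ceiling).

Consecutive equal states are merged into segments. Each segment is then
tested for differential methylation with the two-sided Wilcoxon rank-sum
test comparing the member β values of the two samples
(`stats::wilcox.test`: exact null distribution for small tie-free samples,
midranks with tie-corrected variance and continuity correction otherwise).
A segment becomes a DMR when |mean Δβ| > `cutoff`, p < `alpha` and it has
at least `minCpgs` member groups; the sign of the mean sets the
hyper-/hypo-methylated label.

### Two-step parameter estimation

Step one estimates the noise scale from the data:
σ̂_ε = MAD(Δβ_i − Δβ_{i−1}) / √2, where MAD carries the usual 1.4826
consistency constant. Successive differences of white noise have variance
2σ_ε², and the median absolute deviation is insensitive to the sparse level
jumps that contaminate the differences — on a two-level track the estimator
recovers the generative σ while the naive standard deviation is inflated
about twofold (see `test-slm.R`). The level-jump scale is tied to the noise
by the signal fraction ω: σ_μ² = ω/(1−ω) · σ_ε². Step two runs Viterbi
with these values. A constant track would give σ̂_ε = 0 and a degenerate
likelihood, so σ̂_ε is floored at 10⁻³ with a warning.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `theta` | 0.1 | — | baseline jump parameter; η ranges over (θ/2, (1−θ)/2) |
| `dNorm` | 1000 | bp | distance scale of η; at d = d_Norm, η = θ − θ² |
| `omega` | 0.9 | — | signal fraction; σ_μ = 3σ_ε at the default |
| `nStates` | 41 | — | level-grid size; 0.05 resolution on [−1, 1] |
| `minCalledSites` | 5 | calls | per-sample coverage filter at the join |
| `cutoff` | 0.3 | Δβ | DMR classification threshold |
| `alpha` | 0.05 | — | rank-sum significance gate (uncorrected) |
| `minCpgs` | 5 | groups | minimum DMR extent |

θ and d_Norm are configuration, not estimated; the defaults place the η
inflection near typical intra-island CpG spacing so that island-internal
CpGs (tens of bp apart) rarely break segments, while CpGs separated by
kilobases change state cheaply. The 41-level grid gives 0.05 resolution,
comfortably below the 0.3 calling cutoff; ω = 0.9 encodes that level jumps
worth calling are a few times the noise scale. A coverage of fewer than 5
calls makes β granular at the ±0.2 level, hence the join filter. The
defaults deliberately report raw p-values — the conventional choice for
this caller — and a Benjamini–Hochberg flag (`bhCorrect`) is available and
off by default. `minCpgs = 5` reflects that the rank-sum test has
essentially no power below n = 4.

Boundary conventions: coordinates are 0-based half-open internally and in
all TSV/BED output; `GRanges` objects returned to the user are 1-based
closed, converted at the boundary. A CpG group's anchor is its start
coordinate; inter-group distances are start-to-start. Groups are
strand-collapsed, as in the frequency-table dialect. Per-read calls are
labelled by strict inequalities (|LLR| must exceed 2.5), so a call at
exactly the threshold is ambiguous and excluded everywhere, including the
entropy windows. CpG density classes use inclusive boundaries (≤2, ≤3,
else >3 CpG/100 bp). Groups covered in only one sample are dropped, not
imputed. DMR→element overlap is any-basepair; when a DMR spans several
elements all are reported, with no priority order.

## Companion statistics

**Enrichment.** The statistic is
log2[(Size_GF^DMR / Size_Total^DMR) / (Size_GF^Genome / Size_Total^Genome)],
where Size_GF^DMR is the total size of DMRs overlapping the feature (the
full width of each overlapping DMR, not the intersection). Significance
comes from Monte Carlo placement: each simulation places n segments with
exactly the observed size multiset, chromosome proportional to length among
chromosomes long enough to hold the segment, start uniform within bounds;
p = (1 + #{simulations at least as extreme}) / (nSims + 1), so p is never 0
and halves its floor when nSims doubles. Extremeness is two-sided, measured
as absolute deviation of the observed/expected *ratio* from the median
simulated ratio: on the log2 scale a zero-overlap simulation is −∞ and
would count as "extreme" against any enrichment, which would inflate
p-values for strongly enriched features; the linear ratio keeps depletion
finite (ratio 0) and preserves the ranking interpretation. The default
nSims = 10⁴ keeps an interactive run cheap; genome-scale analyses
conventionally use 10⁶, and the parameter is exposed everywhere. Placement
is unconstrained by mappability or assembly gaps; an exclusion list can be
emulated by shrinking the chromosome-size table.

**Methylation entropy.** Over a window of b consecutive CpG sites, every
read with an unambiguous call at all b sites contributes one binary
pattern, and ME = (1/b) Σ −(n_i/N) log2(n_i/N): 0 when all reads agree, 1
when all 2^b patterns are equifrequent. The per-site normalisation (1/b
with log base 2) is what makes those anchors exact. Windows slide one site
at a time; windows with fewer than `minReads` (default 5) informative reads
are skipped and counted, and a feature with no eligible window is flagged
undefined rather than zero. The plug-in entropy estimator is biased
downward at low coverage (about (2^b − 1)/(2N ln 2) bits), which is why the
b = 3 default and a minimum of a handful of reads are sensible together.

**Annotation.** Genic elements are derived per transcript, strand-aware:
1to5Kb = [TSS−5000, TSS−1000), promoter = [TSS−1000, TSS) (mirrored on the
minus strand), first exon, internal exons, introns, and — when CDS bounds
are annotated — 5'UTR and 3'UTR as the exonic sequence outside the CDS.
Non-first exons are trimmed of UTR sequence so that, within a transcript,
the only overlapping pair is the documented 5'UTR-inside-first-exon
containment. Region groups follow the standard vocabulary: Reg = {1to5Kb,
promoter, 5'UTR, first exon}, GB = {internal exons, introns}; enhancer
targets are consumed as a precomputed two-column table, never predicted.

## The synthetic benchmark

The generator (`simConfig`/`simulateMethPair`) emulates the data structure
the caller assumes, at desk scale:

* CpG positions from a two-rate spacing process: dense islands (mean 20 bp
  between CpGs, ~25 CpGs per island) alternating with sparse background
  (mean 150 bp, ~75 CpGs between islands) — about 1 CpG/100 bp overall,
  the density regime long reads resolve and short-read assays do not;
* bimodal baseline methylation (islands β = 0.1, background β = 0.9);
* planted DMRs shifting β by ±effect in the test sample only, clipped to
  [0, 1]; hyper-methylated DMRs are planted inside islands and
  hypo-methylated ones in the background, so the full effect survives
  clipping at any effect ≤ 1;
* reads covering `readLengthCpgs` consecutive CpGs with uniform random
  starts (per-site coverage ≈ Poisson); per-read, per-site methylation is
  Bernoulli with a probability drawn from Beta(βφ, (1−β)φ) through a
  shared read-level quantile, giving beta-binomial marginal counts
  (precision φ = 20 by default; `noiseModel = "binom"` switches the
  overdispersion off) and within-read pattern correlation for the entropy
  module;
* LLR values drawn beyond the calling threshold with a configurable
  ambiguous fraction (default 5%) exercising the call filter.

Everything is deterministic given the seed, and outputs are emitted in the
same TSV dialects the readers consume.

Scoring is CpG-level (each group labelled hyper/hypo/null by truth and by
calls; direction mismatches count against both precision and recall) and
DMR-level (same-direction matching at ≥50% reciprocal overlap, a
configurable artifact choice). Strata by CpG-density class report, in
particular, recall in the ≤2 CpG/100 bp stratum — the sparse regions that
motivate long-read calling.

What the generator does *not* emulate: mappability and coverage biases,
strand asymmetries, multi-CpG calling groups (all simulated groups contain
one motif), hemimethylation, copy-number-induced β shifts, or correlated
biological replicates. A green benchmark therefore demonstrates that the
segmentation, testing and scoring machinery is correct and well calibrated
under the stated noise model — not that real tumour pairs will reach the
same operating point. The default benchmark conditions (|Δβ| = 0.5,
20 CpGs/DMR, 20× coverage, 50 replicates; 1 Mb chromosome ≈ 8,500 CpG
groups) were fixed once as the study conditions and are the sizes used by
the test suite and the acceptance script.

## Numerical choices and degenerate inputs

* Log-space throughout the decoder; the truncated-Gaussian normaliser is
  computed per level once.
* Viterbi ties break toward the lower state index (deterministic output).
* σ̂_ε floored at 10⁻³ with a warning on (near-)constant tracks; parameter
  estimation refuses tracks shorter than 10 groups, and the pipeline skips
  such chromosomes with a warning.
* Segments with fewer than 2 groups are untestable: p = 1 with a warning.
* Empty overlap in enrichment reports log2 = −∞ ("depleted below
  resolution"); a zero-size feature is an error; the add-one correction
  keeps empirical p ≥ 1/(nSims + 1).
* Frequency tables recompute β = called_sites_methylated / called_sites on
  read, so round-trips are bit-exact even though the printed frequency
  column is rounded.
* On tracks simulated from the generative model itself, the MAP path
  merges level jumps below the noise floor — increments with
  |δ| ≲ 2σ_ε are not resolvable by any decoder at 0.05 grid resolution —
  so segment-count recovery is assessed on resolvable jumps
  (|δ| ≥ 2σ_ε), where the decoded count matches the planted count within
  ±20% (see `test-slm.R`).

## Known limitations

* Two samples only; no covariates, replicates or joint multi-sample
  segmentation.
* Posterior marginal (forward–backward) decoding and EM refinement of θ
  are out of scope; θ and d_Norm are user configuration.
* The enrichment null ignores mappability and GC matching.
* 5hmC, raw signal processing, basecalling and alignment are upstream of
  this package.
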