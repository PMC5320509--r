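---
title: "Identifying and analysing transcribed enhancers with ernakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and analysing transcribed enhancers with ernakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernakit)
library(GenomicRanges)
```

## The problem

Active enhancers are transcribed by RNA polymerase II into short, unstable
non-coding transcripts — enhancer RNAs (eRNAs) — whose abundance tracks
enhancer activity. In strand-specific total RNA-seq of a tissue, eRNA
signal is intergenic read enrichment that survives two confounders:
polymerase read-through past gene ends, and genic antisense signal.
`ernakit` implements a complete workflow that identifies transcribed
enhancers from such data, vets them against H3K27ac chromatin marks,
tests their differential expression between two conditions (labelled
`WT` and `HD` throughout, after the wild-type vs Huntington's-disease
striatum setting the workflow was designed for), and integrates
super-enhancer annotations, RNAPII occupancy and transcription-factor
motif content.

## The identification model

**Genic masking.** Every gene span from the annotation (13 masked
biotypes, `default_mask_biotypes()`) is extended 3 kb upstream of the TSS
and 10 kb downstream of the gene end (`build_genic_mask()`). The
asymmetry is deliberate: read-through transcription continues downstream
of the termination site and decays over kilobases, while upstream
contamination is mostly promoter-proximal. Masking uses the full gene
span rather than per-transcript intervals — the mask is a union over
isoforms anyway, and per-gene spans make the exclusion conservative and
reproducible across annotation versions.

**Strand-aware filtering.** The libraries sequence the strand produced
during first-strand cDNA synthesis, so a read maps *antisense* to its
source RNA. A genic transcript therefore produces reads on the strand
opposite its gene, and `filter_reads()` removes exactly those: reads
overlapping a mask region (>= 1 bp) whose strand differs from the
read's. Reads on the gene's own strand are retained — relative to the
gene they represent antisense transcription, a candidate regulatory
signal. Split-mapped (spliced) reads are removed unconditionally, as
splicing marks mature genic transcripts. Unstranded reads are rejected
with an error rather than guessed at.

**Poisson peak detection.** Putative eRNAs are regions of read
enrichment in the filtered data, detected as in ChIP-seq peak calling
(`call_peaks()`): each read's 5' end is shifted by half a fragment
length along its strand, extended to a fragment-sized tag, and positions
whose pileup exceeds a Poisson upper-tail threshold (p < 1e-4) against a
genome-wide background rate become candidates. Duplicates are kept —
eRNA loci are short and genuinely accumulate identical fragments. The
fragment length is estimated from the data by maximising the
cross-correlation between the strand-specific 5'-end profiles
(`estimate_shift()`, ties to the smallest lag). Significant runs
separated by at most one fragment length are merged: sub-fragment gaps
are below the resolution of fragment-sized tags, and without the merge a
locus near the detection threshold shatters into many slivers. A
`local_lambda` mode (used for RNAPII peaks, p < 1e-5, the tool-default
setting in this workflow) additionally re-estimates the background in 1,
5 and 10 kb windows around each candidate and keeps the maximum, making
calls robust to local coverage structure. The caller intentionally does
not reproduce any specific tool's numerical output; it implements the
stated model with the stated parameters.

**Island-based vetting.** H3K27ac enrichment is broad, so it is called
with a window/gap island model (`call_islands()`): 200 bp windows are
eligible when their deduplicated read count is Poisson-significant
(window p 0.2) against the genome-wide rate over the effective genome
fraction (0.77); eligible windows separated by at most 600 bp of
ineligible sequence merge into islands; an island's score is the sum of
`-ln P(count)` over its eligible windows. The score threshold is chosen
so that the expected number of equal-or-better-scoring islands under the
background model is at most the E-value (1000); that expectation is
estimated by simulating the null window-count process (5 replicates,
fixed internal seed, caller RNG preserved) rather than by an analytic
island-probability recursion — a documented approximation that is
accurate at these genome sizes. With a control library, per-island
chip-vs-control Poisson tests are BH-adjusted and filtered at FDR 1e-2.
Candidates from both conditions are merged into one unique region set
(`merge_candidates()`), and regions overlapping an island in *either*
condition enter the catalogue (`filter_by_h3k27ac()`); support is
recorded per condition so a stricter both-condition policy remains
recoverable. Catalogue records are unstranded, since enhancers are
commonly transcribed bidirectionally.

## Differential expression

Reads are counted per catalogue region (>= 1 bp overlap, largest
overlap wins, leftmost on ties; `count_reads()`), normalised with
median-of-ratios size factors (`size_factors()`), and tested per region
with a negative binomial Wald test (`differential_test()`): per-region
dispersions come from a within-condition method-of-moments estimate,
floored at 1e-8 and shrunk 50/50 toward a fitted `a0/mu + a1`
mean-dispersion trend; an NB GLM with log link and size-factor offsets
is fitted per region with the plug-in dispersion and the condition
coefficient tested two-sidedly. Three numerical details carry the
test's calibration at replicate-level sample sizes. First, the Wald
standard errors use a fixed scale of one, because the NB variance is
fully specified by the plug-in dispersion — re-estimating a residual
scale from the few residual degrees of freedom makes the test badly
anticonservative whenever that scale is underestimated by chance.
Second, with near-constant region means the `1/mu` trend design is
almost collinear, so when a fitted trend coefficient leaves its
admissible range the trend is refitted under the constraint instead of
clipped (clipping one coefficient while keeping its compensating
partner shifts the dispersion of an entire dataset at once). Third, the
Wald statistic is referred to a Student-t distribution with
`4 * (n - 2)` effective degrees of freedom, a Satterthwaite-style
account of the dispersion being estimated rather than known: the shrunk
dispersion carries about a quarter of the variance of the `(n - 2)`-df
per-region estimate, and with a plain normal reference the null
rejection rate at the 4+4 design sits visibly above nominal and the
BH-level false discovery proportion above 0.1. This pipeline is
deliberately
simpler than shrinkage-based DE engines (no empirical-Bayes dispersion
moderation, no outlier handling, no independent filtering); its
calibration is verified by simulation in the test suite (null rejection
0.035–0.065 at p < 0.05; >= 80% power for 4-fold effects at a
catalogue-scale design), and an externally produced DE table can be
substituted for this stage. Statuses use BH-adjusted p-values at
`alpha = 0.05` with no fold-change floor (`classify_status()`).

## Integration

- `assign_nearest_gene()` associates each eRNA with the gene whose TSS
  is nearest the eRNA midpoint (any strand; lexicographic tie rule).
- `overlap_enrichment()` tests over-representation of a property in a
  status class against the catalogue rate with a 1-df
  observed-vs-expected chi-square; "enriched" additionally requires the
  observed count to exceed expectation, at p < 1e-2. A full 2x2
  independence test would differ only by the universe margin; the
  goodness-of-fit form matches how observed and expected class counts
  are compared here.
- `rnapii_accounting()` crosses RNAPII peak presence per condition with
  eRNA status (lost = WT peak without HD peak, gained = the reverse) and
  reports integer-rounded percentages, the granularity used in
  catalogue-level reporting; `rnapii_rates()` exposes the bare
  arithmetic for externally supplied counts.
- `size_profile()` sums the widths of islands overlapping each eRNA per
  condition and compares status classes with a Wilcoxon rank-sum test —
  broad (super-enhancer-like) islands at down-regulated eRNAs appear as
  a larger down-class median.

## Motif enrichment

`scan_pwm()` scores every window of a sequence set on both strands with
log2 odds against a 0-order background and converts scores to p-values
with an exact discretised distribution (1/1000 of the score range per
bin, computed by dynamic programming over positions); hits are windows
with p < 1e-4, a PWM pseudocount of 1e-3 guards zero entries, and
windows containing `N` never match. Note a hard limit: a motif of width
`w` cannot beat `p = prod(bg[consensus])`, so under a near-uniform
background motifs shorter than 7 bp cannot reach the 1e-4 default at
all.

`enrich_motifs()` measures enrichment of each motif in a target class
(for example the down-regulated eRNAs) against `n = 100` size-matched
random draws *from the eRNA catalogue itself*, which cancels the
nucleotide-composition bias of enhancer sequence; genome-wide draws are
appropriate only for the GC-content comparison (`gc_content()`). The
statistic is `z = (x - mu) / sigma` over the resample counts (sd with
denominator n-1), with a one-sided upper-tail normal p-value (the
question is enrichment; depletion can be read off the sign) and BH
adjustment across motifs. Size matching draws uniformly among available
catalogue regions within 20% relative size difference (falling back to
the nearest size): a strictly deterministic closest-size rule would
return nearly the same set in every resample whenever region sizes are
distinct, collapsing `sigma` to zero and with it the statistic. When
`sigma` is still zero the result is flagged degenerate instead of being
dropped. Per-region hit counts over the catalogue are computed once per
motif, so the 100 resamples are sums over cached counts, and the scan
background is estimated from catalogue sequence so targets and controls
share one score model.

## The synthetic study

`simulate_erna_dataset()` generates the two-condition dataset the
package is validated on. Defaults describe the study conditions: a 2 Mb
two-contig genome; 40 protein-coding genes; 60 intergenic enhancers of
which 12 are super-enhancer-like; background GC 0.42 vs enhancer GC
0.55; four replicates per condition at 4e5 reads per condition; 50 bp
reads from 200 bp fragments; enhancer transcription at 10x the
intergenic background; 15 enhancers planted down (HD/WT fold 0.25) and
8 up (fold 4) with NB replicate dispersion 0.05; a 7 bp consensus motif
planted centrally in half of the down enhancers; H3K27ac islands of
0.8–2 kb (typical) or 8–15 kb (super), shrunk to 60% width in HD at
down enhancers; RNAPII peaks lost in HD at 40% of down enhancers and
gained at 25% of up enhancers; 2% of reads flagged split-mapped to
exercise the split filter.

Design choices worth knowing:

- Reads are single-end *fragment-end* reads: a fragment yields a `+`
  read at its left end or a `-` read at its right end, so the
  strand-specific 5' profiles around a transcribed locus sit one
  fragment length apart and `estimate_shift()` can recover it from the
  data, as fragment-size estimation does on real libraries. Genic reads
  map antisense to their gene (first-strand chemistry) and 15% of them
  continue past the gene end with exponentially decaying read-through
  (scale 2 kb) — the artifact the 10 kb downstream mask extension
  exists to absorb. Upstream contamination is represented by the
  uniform background component rather than a dedicated promoter model.
- Super-enhancers broaden the *island*, not the transcribed span (all
  spans are 0.6–1.5 kb). Tying span size to the super class would let
  size-matched motif resampling reconstruct the down class from sizes
  alone and make its null degenerate.
- Down status is assigned to super-enhancers first (12 of 15 by
  default), planting the broad-island/down and super-enhancer/down
  associations the integration analyses are meant to detect.
- Elements are laid out with >= 18 kb clearance between enhancers and
  gene spans and >= 16 kb between enhancers, so no planted enhancer —
  and no island of one, even the broadest — can intersect a default
  extended genic mask. A layout that cannot satisfy these constraints
  raises an error rather than silently crowding elements.
- Everything is deterministic under the config seed; the generator
  saves and restores the caller's RNG state.

What the simulation does *not* model: real genome sequence and
mappability, splicing (split reads are a flag, not spliced alignments),
promoter-antisense transcription, batch effects, or replicate-level
library-composition biases. Passing the end-to-end tests therefore
demonstrates that the pipeline's logic and statistics behave as
specified under controlled conditions, not that any particular
biological dataset will yield a catalogue of a given quality.

## Numerical choices and edge cases

- Intervals are 1-based closed `GRanges` in memory (the native
  Bioconductor convention); BED I/O converts to and from 0-based
  half-open coordinates at the file boundary, and BED-style adjacency
  (end of one region equals start of the next) is never counted as
  overlap.
- Poisson tail computations use log-space tails, so peak scores do not
  overflow to infinity at extreme enrichment.
- Summits, correlation lags and count-assignment ties all resolve
  leftmost; nearest-gene ties resolve to the lexicographically smaller
  gene id.
- The shift cross-correlation is computed with power-of-two FFTs; true
  correlations are integer counts, so results are rounded before the
  argmax to keep FFT noise from breaking ties.
- `size_factors()` errors when no feature has all-positive counts
  instead of silently switching to a pseudo-reference.
- Degenerate motif resampling (`sigma = 0`) reports `z = 0, p = 1` when
  the observation does not exceed the resample mean, and an infinite
  `z` with a sentinel near-zero p when it does, always flagged.

## Problem sizes used in validation

The bundled tests run the complete pipeline end-to-end on five seeds of
the default 2 Mb / 60-enhancer study (recovering planted enhancers with
sensitivity >= 0.90 and precision >= 0.95), check each core operation
against independent brute-force implementations on at least a hundred
randomised small instances, and verify statistical calibration with
2000-row null count matrices and 10^4 motif-null simulations. These
sizes were chosen so the whole suite completes in a few minutes on a
single CPU while keeping every estimate's Monte Carlo error well inside
the asserted bounds.

## Known limitations

- The peak and island callers implement the stated statistical models,
  not bug-for-bug reimplementations of any external tool; boundary
  coordinates can differ from those tools by design.
- The differential engine is a calibrated plug-in-dispersion Wald test;
  with very few replicates or very low counts a shrinkage-based engine
  will be more powerful, and can be imported in its place.
- The island E-value threshold is Monte Carlo-estimated; at extreme
  genome sizes or rates the fixed five-replicate default may need
  raising.
- Motif p-values assume the resample counts are approximately normal;
  for very rare motifs (expected counts near zero) the Z approximation
  is coarse and the degenerate flag should be heeded.
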