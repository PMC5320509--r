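# ernakit

Identification and differential analysis of transcribed enhancers
(enhancer RNAs, eRNAs) from strand-specific total RNA-seq, for
regulatory-genomics analyses of two-condition designs — the motivating
setting is wild-type vs Huntington's-disease mouse striatum (conditions
`WT` and `HD` throughout).

Active enhancers produce short non-coding transcripts whose abundance
tracks enhancer activity. `ernakit` turns stranded RNA-seq alignments
into a vetted eRNA catalogue and its dysregulation profile:

1. **Genic masking & read filtering** — gene spans extended −3 kb/+10 kb
   (TSS/TES, strand-aware) exclude polymerase read-through; split reads
   and reads overlapping a mask region on the opposite strand (the genic
   signal under first-strand library chemistry) are removed.
2. **Peak detection** — a Poisson-background caller (p < 1e-4, duplicates
   kept, fragment shift estimated by strand cross-correlation) finds
   read-enriched intergenic regions per condition; a local-lambda variant
   (p < 1e-5) serves RNAPII ChIP-seq.
3. **H3K27ac vetting** — a SICER-style window/gap island caller
   (window 200, gap 600, E-value 1000, FDR 1e-2, effective genome
   fraction 0.77) marks active chromatin; merged candidates overlapping
   an island in either condition form the eRNA catalogue.
4. **Differential expression** — median-of-ratios normalisation
   (`s_j = median_i k_ij / (prod_v k_iv)^{1/m}`) and a negative binomial
   Wald test with trend-shrunk method-of-moments dispersions; BH
   adjustment; statuses down/up/unchanged at padj < 0.05.
5. **Integration** — nearest-TSS gene association, observed-vs-expected
   chi-square enrichment (`chi2 = sum (O−E)^2/E`, 1 df, p < 1e-2),
   RNAPII peak loss/gain accounting, super-enhancer overlap, island
   size profiles (Wilcoxon).
6. **Motif enrichment** — FIMO-style PWM scanning with exact
   DP-discretised score p-values, and the resampling statistic
   `z = (x − mu) / sigma` where `mu`/`sigma` summarise motif occurrence
   over n = 100 size-matched random eRNA sets, one-sided normal p, BH
   across motifs.

A synthetic-data generator (`simulate_erna_dataset()`) produces a fully
specified two-condition study — genome, genes, enhancers and
super-enhancers, stranded reads with read-through, islands, RNAPII
peaks, planted motifs and ground truth — so the entire pipeline is
testable offline.

## Worked example

```r
library(ernakit)

sim <- simulate_erna_dataset(sim_config(seed = 17))
motif <- consensus_pwm(sim$config$motif_consensus)
report <- run_erna_pipeline(
  sim$rna_reads, sim$genes, sim$islands, sim$chrom_sizes,
  rnapii = sim$rnapii, super_enhancers = sim$super_enhancers,
  genome = sim$genome, motifs = list(motif), seed = 17)
report
#> eRNA analysis report
#>   candidates per condition: WT 60, HD 60
#>   merged candidate regions: 60
#>   H3K27ac-supported eRNAs:  60
#>   down / up / unchanged:    15 / 12 / 33
#>   RNAPII+ eRNAs WT/HD:      58 / 54

score_recovery(sim$truth, report$catalogue)[c("sensitivity", "precision")]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 1

report$motif_table
#>     motif x   mu    sigma        z           p        padj degenerate
#> 1 TGACTCA 9 4.78 1.673199 2.522114 0.005832589 0.005832589      FALSE
```

The funnel reads: 60 read-enriched candidate regions per condition merge
into 60 unique regions, all island-supported, of which 15 are called
decreased and 12 increased in `HD` (15 down / 8 up were planted; the
extra up calls are true NB sampling excursions at this depth).
`report$se_enrichment` shows the down class enriched for super-enhancer
overlap, `report$rnapii_summary` the RNAPII peak losses concentrated in
the down class, and `report$motif_table` above shows the planted
consensus enriched in down-eRNA sequence (x = 9 occurrences observed
against mu = 4.78 +/- 1.67 expected over 100 size-matched resamples).

File-based inputs go through `read_gtf()`, `read_alignments()` (SAM
text or BED), `read_bed()`, `read_jaspar()`/`read_meme()`; results are
plain `GRanges`/data.frames, exportable with `write_bed()`.

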