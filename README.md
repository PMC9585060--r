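# peakscape

Peak-centric integration of transcription-factor ChIP-seq binding with
chromatin state and differential expression.

## The problem

A transcription factor's genome-wide binding sites (ChIP-seq peaks) only
become interpretable when they are placed in genomic and regulatory
context. Given a peak set, gene models, companion epigenomic tracks
(ATAC-seq open chromatin, histone-modification ChIP-seq) and a
differential-expression (DE) table from a factor-mutant versus control
comparison, `peakscape` answers four questions:

1. **Where does the factor bind?** Each peak is classified by its summit
   into *promoter* (the 3 kb immediately upstream of a TSS,
   strand-aware), *intragenic* (gene body plus 300 bp past the TES), or
   *distal intergenic*, and assigned to the gene with the nearest
   promoter (with reassignment of peaks landing on pseudogenes nested in
   another gene's body).
2. **Is binding coupled to chromatin state?** Colocalization between the
   peak set and a companion set is tested on a binned genome with an
   upper-tail hypergeometric test. With the genome tiled into $N$ bins,
   $K$ of them hit by set A, $n$ by set B and $a$ by both,

   $$p = P(X \ge a), \quad X \sim \mathrm{Hypergeom}(N, K, n), \qquad
     \mathrm{OR} = \frac{a\,d}{b\,c}$$

   with the Haldane–Anscombe +0.5 correction when a cell is empty, and a
   width-preserving permutation null as a model-free cross-check.
3. **How strong is the signal at peaks?** Track reads within 1 kb of
   each peak are normalized to window width and sequencing depth
   (RPKM = count / window-kb / (library/10⁶)), with peak-centered and
   scaled TSS→TES metagene profile matrices, per-stratum summaries, and
   two-sided Mann–Whitney rank-sum comparisons (exact by enumeration for
   small samples, tie-corrected normal approximation otherwise).
4. **Which genes does the factor regulate directly?** DE rows are
   classified as *activated* (log2FC ≤ −0.5 and FDR < 0.05, fold change
   expressed as mutant over control), *repressed* (log2FC ≥ +0.5,
   FDR < 0.05), *filtered* (below 25 mean counts in both genotypes) or
   *unchanged*; a *direct* target is an activated or repressed gene that
   is the assigned gene of at least one peak.

The package also scans sequences on both strands for the factor's IUPAC
consensus (default `GGTTAATNATTAAC`), and ships a fully seeded
synthetic-data generator that plants known region compositions,
bin-level colocalization odds ratios, fold enrichments, direct-target
sets and motif instances, so that every stage can be validated by
parameter recovery without any external download.

## Worked example

```r
library(peakscape)

cfg <- synthetic_config(seed = 7, coloc_odds_ratio = 8, enrichment_fold = 2)
sim <- simulate_study(cfg)            # genes, peaks, tracks, DE, sequence

summarize_regions(sim$annotations)
#>        region_class   n  pct
#> 1          promoter 114 22.8
#> 2        intragenic 188 37.6
#> 3 distal_intergenic 198 39.6

coloc_test(sim$peaks, sim$companion_peaks, sim$chrom_lengths)
#> Peak colocalization
#>   244 A peaks overlap B (48.8%)
#>   bins (both/A/B/neither): 272/630/279/5399 of N = 6580 (width 304 bp)
#>   hypergeometric p = 1.78e-101, odds ratio = 8.35

call_direct_targets(sim$de, sim$annotations)
#> Direct target calls
#>   activated: 52, of which bound (direct): 52 (100%)
#>   repressed: 50, of which bound (direct): 50 (100%)

peaks_with_motif(sim$peaks, sim$genome_seq)$fraction_with_motif
#> [1] 0.332
```

The 500 planted summits were drawn with the 26/37/37% promoter/
intragenic/distal mix, and classification recovers it up to multinomial
noise. The companion peak set was planted with a bin-level odds ratio of
8; the binned hypergeometric test estimates 8.35 and rejects
independence. All 100 planted direct targets are recovered (the two
extra activated calls are planted spurious-significance genes that
happen to be bound), and the motif fraction reflects the 30% of peaks
that carry a planted consensus instance.

File-based workflows use the same functions via `read_peaks()`,
`read_gene_models()`, `read_coverage()`, `read_de_table()` and
`run_pipeline()` (YAML config, JSON report); a thin command-line wrapper
lives at `inst/scripts/peakscape.R` with `simulate`, `run`, `annotate`,
`coloc`, `targets` and `motif` subcommands.

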