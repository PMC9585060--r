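---
title: "Methods: peak-centric integration of TF binding, chromatin state and expression"
author: "peakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak-centric integration of TF binding, chromatin state and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices
behind `peakscape`, in the spirit of a statistical-methods appendix. It
states no empirical result beyond what the package's own tests and
`scripts/acceptance.R` compute.

## Coordinate contract

Every interval in the package is 0-based half-open (`[start, end)`, the
BED convention). GTF input and output are converted at the boundary
(1-based inclusive to half-open and back), so no other module ever sees
two conventions. The TSS of a plus-strand gene is `start`; of a
minus-strand gene, `end - 1`. "Upstream" and "downstream" are always
strand-aware. Coverage tracks store one *anchor* position per read; for
interval-shaped read records the anchor is the interval midpoint. A read
is inside a window exactly when its anchor is — there is no fractional
overlap. These single-point rules make every count deterministic and
make brute-force oracles trivial to write.

## Region classification and gene assignment

A peak is reduced to a classification point: its summit when the peak
caller reported one, otherwise the interval midpoint. Binding-site
classification is a statement about a site, not a span, so a point rule
keeps the promoter/intragenic/distal partition well defined even when a
wide peak straddles several regions.

The windows, with defaults:

* promoter — within `upstream` (3000) bp strictly upstream of any TSS;
  signed distance $d \in [-3000, 0)$;
* intragenic — inside any gene body, or within `downstream` (300) bp
  past any TES;
* distal intergenic — everywhere else.

When windows of different genes overlap, precedence is promoter >
intragenic > distal: the categories are exclusive and promoter
proximity is the biologically prioritized call. Each peak is assigned to
the gene minimizing `|point − TSS|`; for promoter-class peaks the
minimum is taken over the genes whose promoter window contains the
point, so the signed distance of a promoter peak always lies inside the
promoter window of its assigned gene. Exact ties are broken by the
lexicographically smallest gene id — an arbitrary but deterministic
rule. When the nearest TSS belongs to a pseudogene and the point lies
inside the body of a non-pseudogene gene, the peak is reassigned to that
host gene; promoter-class calls are exempt so the promoter-distance
invariant holds. There is no cap on assignment distance by default
(`max_tss_distance` provides one), because nearest-promoter assignment
is the only binding-to-gene link the pipeline constructs.

Subregions are descriptive only. With no CDS in the gene-model input,
5′UTRs are proxied by the first exon in transcription order; everything
else in a body is `exon` or `intron`, and `downstream<=300` marks the
post-TES window.

## Colocalization testing

The peak-wise overlap fraction counts each A peak once if it shares at
least one base pair with any B peak (half-open intervals: abutting peaks
do not overlap). For the significance test the genome is tiled into
non-overlapping bins; a bin is *hit* by a set when any of its peaks
overlaps it. The default bin width is the median A peak width, which
puts the universe size on the natural scale of the binding-site data and
is reproducible from the inputs alone. From the 2×2 bin table
(both $a$, A-only $b$, B-only $c$, neither $d$; $N = a+b+c+d$) the
p-value is the upper-tail hypergeometric probability
$P(X \ge a)$ with $K = a+b$ marked bins and $n = a+c$ draws, accumulated
in log space from `lchoose` terms so the computation is stable for
universes of millions of bins. The odds ratio is $ad/bc$ with the
Haldane–Anscombe +0.5 added to all four cells when any cell is zero —
finite, standard, and flagged by construction rather than silently
dropped.

Because the bin universe is a modelling choice, a permutation null is
provided: B peaks are re-placed uniformly on their own chromosomes with
widths preserved and the A-overlap count is recomputed;
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}} + 1)$. The
test suite checks that under a planted null both the hypergeometric and
the permutation p-values are uniform, and that planted odds ratios of 4
and 16 are recovered within ±20% at a ~20,000-bin universe (median over
20 draws).

## Signal quantification

RPKM at a peak uses the window `[start − flank, end + flank)` with
`flank = 1000` by default: the peak span participates because depth
normalization is relative to the queried width, and the span-plus-1-kb
reading keeps wide and narrow peaks comparable. A summit-anchored
fixed-width window is available via `anchor = "summit"`. Windows
truncate at chromosome edges with the width recomputed.
`rpkm = count / window_kb / (library_size/10^6)` is invariant under
joint rescaling of counts and depth.

Peak-centered profiles bin `±half_window` (2000) around the summit at
`bin_width` (50) bp; metagene profiles rescale each gene body linearly
onto `body_bins` (100) bins with fixed-resolution 3-kb flanks
(`flank_bins` = 100, i.e. 30 bp per flank bin), reversing minus-strand
rows so columns always read TSS→TES. Genes shorter than `body_bins` bp
cannot be rescaled meaningfully and are skipped with a warning count.
Before normalization, per-row bin counts sum to the reads in the row's
window — a conservation property the tests assert against an unindexed
per-read loop.

Published heatmap rendering parameters (window and bin sizes) are not
part of the upstream record; the defaults above are this package's own
choices.

## Statistical cores

`hypergeom_sf` is shared by the colocalization test and exposed
directly. `mann_whitney` computes the rank-sum U with midranks for ties.
The p-value branch is part of the contract: exact by full enumeration of
rank assignments when `min(n1, n2) ≤ 8` and the pooled data are
tie-free (feasible and exact at that size), otherwise a normal
approximation with tie-corrected variance and a 0.5 continuity
correction (recorded in the result, since reference analyses rarely
state whether they corrected). Two-sided p-values double the smaller
one-sided tail and cap at 1. The suite verifies the exact branch against
the full Wilcoxon distribution, the normal branch against
`wilcox.test`, invariance under monotone transforms, and a type-I error
within [0.04, 0.06] at α = 0.05 over 10,000 null replicates.

Wilcoxon panels in reports are unadjusted, one test per printed
comparison, matching common practice for figure-panel contrasts; a
Bonferroni flag is available. Significance stars follow the legend
cutpoints literally, including the mixed operators: `****` p ≤ 1e-4,
`***` p ≤ 1e-3, `**` p ≤ 0.01, `*` p < 0.05, `ns` p ≥ 0.05 — so exactly
0.05 is `ns` and exactly 0.01 is `**`.

## Direct-target calling

The DE table's `log2fc` is defined as mutant relative to control, so
genes *activated* by the factor (higher in control) have negative
values — a sign convention worth stating prominently because flipping it
silently swaps activated and repressed. Thresholds: |log2FC| ≥ 0.5
(inclusive), FDR < 0.05 (strict), and at least 25 mean counts in one or
both genotypes; rows failing the count filter are `filtered` before any
fold-change logic. Inclusiveness at the fold-change boundary is a
package decision; the FDR operator is strict as printed. A gene is
*bound* when it is the assigned gene of ≥1 peak (optionally within
`max_tss_distance` of the TSS); *direct* = bound ∧ (activated ∨
repressed). Percentages are `round(100 · n_direct / n, 1)` — note that
one published repressed percentage (24.1% for 526/2223) does not match
this arithmetic (23.7%); the package reproduces the arithmetic, not the
misprint.

## Motif scanning

The consensus `GGTTAATNATTAAC` is matched exactly as an IUPAC pattern on
the plus strand and as its reverse complement for minus-strand hits,
with forward-strand coordinates throughout; overlapping hits are all
reported. An `N` in the *subject* matches only `N` positions of the
pattern — an unknown base should never satisfy a constrained position.
This semantic is why the matcher is implemented in the package (a
vectorized sliding comparison) rather than delegated to a generic
ambiguity-aware matcher, which treats subject `N` permissively.
Mismatch tolerance defaults to 0 (`max_mismatch` raises it); no PWM is
used because only a consensus string, not a matrix, is part of the
upstream record. The scanner is verified against a naive per-offset
oracle and a strand-reflection closure property.

## Synthetic data: what it emulates and what it does not

The generator draws, per named RNG substream of one master seed (so
adding a generator never perturbs another, and all outputs are
byte-reproducible):

* gene models — non-overlapping genes, ≥3.4 kb apart (3 kb promoter +
  300 bp downstream window + margin, so planted region classes are
  unambiguous under the precedence rule), Bernoulli(0.5) strands, 1–5
  exons, biotypes from a protein-coding-dominated mix;
* peaks — summits planted per a region mix defaulting to 26/37/37%
  promoter/intragenic/distal, the composition observed for the factor;
  lognormal widths around 300 bp;
* a companion peak set — bins of the median peak width are hit with
  probability `p1` inside primary-hit bins and `p0` outside, with
  `p1/(1−p1) = θ·p0/(1−p0)`, each companion peak placed entirely inside
  its bin so the planted bin-level odds ratio is exactly θ in
  expectation;
* coverage — Poisson background at `background_rate` reads/bp, with the
  total rate raised to `enrichment_fold ×` background inside signal-peak
  windows (span ± 1 kb, matching the RPKM query window so the planted
  fold is what RPKM recovers);
* a DE table — planted direct targets drawn from bound genes with
  |log2FC| ≥ `lfc_effect` and FDR < 0.05; null genes with small fold
  changes and FDR ≥ 0.05 except a `fdr_noise` fraction of spurious
  significant calls; a `frac_low_expressed` fraction below the count
  filter;
* genome sequence — uniform ACGT with consensus instances written
  centered on a `motif_fraction` sample of peak summits.

The default scale (2 chromosomes × 1 Mb, 200 genes, 500 peaks) runs in
seconds on one CPU; the acceptance checks scale individual axes up
(5000 peaks for composition recovery, ~20,000 bins for odds-ratio
recovery, 10-Mb genomes for the 1.3× RPKM contrast at 500 vs 500 peaks)
while keeping the whole suite desk-sized. What the generator does *not*
emulate: read-level sequences, fragment-size and GC bias, mappability
structure, overlapping or nested real gene architectures, and the
correlation structure of real chromatin marks. Passing recovery tests
therefore demonstrates the correctness of the computations under the
stated models, not robustness to every artifact of real libraries.

## Numerical and degenerate-input choices

Tail sums use log-space accumulation with `logsumexp`; probabilities cap
at 1 against round-off. Empty peak files parse to empty sets; an empty
A set is an error for overlap counting (the fraction is undefined) while
an empty B set returns zero. Zero-variance rank-sum inputs return p = 1.
Windows clamp at position 0 and chromosome ends. Summit positions,
where present, must lie inside their peak; violations are format errors
with line numbers. Generated companion sets with θ = 0 share no bins
(and hence no base pairs) with the primary set.

## Known limitations

* The hypergeometric universe depends on the bin width; odds ratios are
  comparable only at a common binning. The permutation test is the
  model-free fallback.
* Nearest-promoter assignment without a distance cap will link very
  distal peaks to genes; use `max_tss_distance` when that matters.
* UTR subregions are exon proxies, not CDS-derived.
* The scanner is consensus-exact; degenerate binding not captured by
  the IUPAC string requires a PWM tool upstream.
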