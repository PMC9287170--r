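---
title: "Quantifying exon inclusion and coordination from barcoded long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exon inclusion and coordination from barcoded long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocoord)
```

## The problem

Single-nuclei long-read sequencing attaches a 16-nt cell barcode and a
12-nt unique molecular identifier (UMI) to each cDNA molecule, then
reads the molecule end to end. Unlike short-read data, each read
reports the *joint* configuration of many transcript elements —
internal exons, the transcription start site (TSS), and the
polyadenylation (polyA) site — of a single molecule from a single
nucleus. That makes three questions answerable:

1. How much does the inclusion of an alternative exon (its percent
   spliced-in, Ψ) differ between cell types?
2. Are pairs of alternative exons used in a *coordinated* way —
   mutually included or mutually excluded within molecules — and does
   bulk-level coordination come from coordination inside individual
   cell types, or from mixing cell types that each use the elements
   constitutively?
3. Are exon choices coupled to the molecule's TSS or polyA site?

`isocoord` implements this analysis end to end, from noisy barcoded
read tables to tested coordination calls, plus the in silico priming
and fragmentation models used to characterize the protocol, and a
synthetic read generator with planted effects so every stage can be
validated against a known truth.

## Tag correction and molecule identification

Long reads have high per-base error rates, so the barcode–UMI 28-mer
on each read is matched against a short-read (Illumina) reference of
28-mers grouped per gene. The sliding-window matcher accepts a
reference tag with at most 1 Hamming mismatch in its first 22 bases
and at most 2 mismatches overall; the unique best match wins and ties
are treated as ambiguous. Groups of reads sharing an observed tag are
then passed through a correction cascade keyed on the Levenshtein
distance (LevD) to the nearest reference tag: LevD 0 is an
Illumina-confirmed molecule; LevD 1–2 is rewritten to the reference
and kept if the corrected triplet is new; LevD > 3 tags are kept as
novel molecules when they are more than 5 edits from every accepted
tag, and merged into an accepted tag at distance 1–2. Two cases are
not covered by that cascade — LevD exactly 3, and distance 3–5 to an
accepted tag — and the package deliberately *discards and counts*
both rather than inventing molecules; configuration switches
(`route_levd3`, `route_mid_distance`) can route them if a user prefers.
Edit distances to accepted molecules are computed on the full 28-mer,
because barcode errors inflate molecules just as UMI errors do.
Finally one read per (barcode, UMI, gene) triplet is retained — the
longest-spanning read, ties broken by read id for determinism.

## Ψ quantification

An *internal* exon is a read block flanked by splice junctions on both
sides; first and last blocks of a read never define exons. For each
exon and context the package counts UMIs that (i) contain the exon
with both splice sites matching exactly (`X_in`; no fuzz window, since
splice-site identity is the defining property), (ii) skip the exon
with at least 50 aligned bases on both sides (`X_out`), (iii) support
one splice site and end on the exon (`X_acc_in`, `X_don_in`), and
(iv) overlap the exon's locus at all (`X_tot`, computed on the read
span so that skipping and intron-retaining molecules are included —
this makes the coverage ratio below a true fraction). The three Ψ
statistics are

$$\Psi_{overall} = \frac{X_{in}+X_{accIn}+X_{donIn}}
                        {X_{in}+X_{accIn}+X_{donIn}+X_{out}},$$

with the acceptor and donor variants dropping the opposite-side
partial count. Alternative exons are those with all three Ψ inside
[0.05, 0.95] (boundary inclusive), coverage ratio
$(X_{in}+X_{accIn}+X_{donIn}+X_{out})/X_{tot} \ge 0.8$, and not
excluded by the novel-exon rule (a non-annotated exon with one or two
annotated splice sites and ≥ 70 bases outside any annotated exon is
treated as intron retention or an alternative splice-site event). The
variability analysis uses the *exclusive* window 0.05 < Ψ < 0.95 with
≥ 10 supporting reads, exactly as each filter is stated; per-cell-type
Ψ is reported only where that cell type has `X_tot` ≥ 10 for the exon.
Cell-type variability is maxΨ − minΨ with categories cut at 0.25 and
0.75; novel-exon quadrants cut both axes at 0.5, boundary inclusive
upward. Disease-exon comparisons use the two-sided Wilcoxon rank-sum
test (exact when both groups are ≤ 25 and untied) and the ratio of
group medians, optionally excluding microexons (≤ 27 nt).

## Coordination testing

For a pair of alternative exons a molecule is informative only when it
yields a *determinate* call for both exons — full inclusion with both
splice sites, or a clean skip with 50-base flanks; exon-terminal
partial support is excluded because it cannot distinguish inclusion
from a truncation artifact. The 2×2 in/out table is scored by:

* **Testability** (the χ² criterion, applied in this printed order):
  *testable* if at least 80% of cells (rounded to nearest integer,
  round-half-to-even) have expected count ≥ 5 and all have ≥ 1;
  otherwise *constitutive* if any row or column has median expected
  count < 5 (that variable is effectively fixed); otherwise *low
  counts*. The implementation is checked exhaustively against a
  brute-force restatement of the rules on all 14,641 2×2 tables with
  entries 0–10 and on random n×2 tables. One consequence of the
  literal rule order is that nonzero 2×2 tables can never be
  *low counts*: shallow tables always expose a row or column median
  below 5 first. Per-class counts are reported so users can audit.
* **Pearson χ²** (no continuity correction by default; a Yates flag
  exists) for testable tables.
* **Odds ratio** with zero cells set to 0.5, and its log. The log
  base is 2 by default: the analysis' only quantitative anchor
  equates an absolute log-odds of 7 with a 128-fold enrichment, which
  forces base 2 even though parts of the method text write log₁₀. A
  `base` argument provides base 10.
* **Benjamini–Yekutieli FDR** across all tested pairs (valid under
  arbitrary dependence), with significance at FDR ≤ 0.05 *and*
  |log-odds| ≥ 1.

Adjacency is annotation-based: a pair is adjacent when no annotated
exon of the gene lies strictly between the two intervals. After FDR,
one pair per gene is retained — the lowest-FDR pair (ties to leftmost
coordinates) by default, or the smallest |log-odds| pair for the
conservation analysis, which correlates the pair's minimum
conservation score with coordination strength. Cell-type tracing
rebuilds each significant pair's table per cell type, recomputes
BY-FDR within the traced set (the analysis text is silent on
re-adjustment; re-adjusting within the traced family is the
conservative choice), and classifies each cell type as significant in
the same or opposite direction as pseudo-bulk, not significant, or
untestable because of low counts or a constitutive exon.

## End-site coordination

For each alternative exon and each end-site kind, molecules with an
assigned site (nearest same-strand peak within 50 bp of the
strand-resolved read end, boundary inclusive, ties to the smaller
coordinate) build an n×2 site × (include, exclude) matrix. A molecule
contributes only if the site respects the positional constraint — a
TSS must lie upstream of the intron preceding the exon and the read
must extend beyond the end of the following intron; mirrored for polyA
sites — and genes with fewer than 25 molecules in the context are
withheld. The same χ² criterion decides testability (df = n − 1, zero
rows dropped from the test), and the effect size is ΔΠ, the largest
minus the smallest per-site inclusion fraction, which is invariant to
count scaling. When tracing into cell types the pseudo-bulk row set is
retained, so a site that one cell type never uses appears as an empty
row and is classified constitutive rather than silently vanishing —
this is what lets the analysis distinguish genuine within-cell-type
coupling from mixtures of cell-type-constitutive configurations.

## Priming and fragmentation models

The priming simulator builds cDNA copies (10 per transcript) with
introns retained at probability 0.15 and a 30-A tail, cuts them into
2-kb fragments plus a shorter end, and classifies fragments as 3'-end
(tail-bearing) or internal. Random-hexamer priming picks a uniform
position; poly(dT) priming picks the longest A-rich stretch (≥ 8 As in
a 10-bp window, merged windows trimmed to their actual A run, ties to
the 3'-most). The protocol text says the sequence *to the right* of
the priming site is kept, but that cannot reproduce its own stated
conclusion that poly(dT) captures entire polyadenylated molecules —
nothing lies right of a terminal tail — so the package defaults to
`keep_side = "upstream"` (the sequence 5' of the priming site), under
which that conclusion holds as an exact property; `literal_right` is
available and flagged. Because a 2-kb cut can split the tail, each
fragment records how many appended-tail bases it carries; "A-poor
internal" properties are evaluated on fragments with none.

The fragmentation simulator keeps a normal-distributed (mean 250 nt,
sd 50) 3' remainder of each read — non-positive draws rejected, then
clipped to [76, read length] — and takes the 5'-most 76 nt of the
remainder as the short-read tag. Coverage profiles split each
transcript into 100 equal bins 5'→3', normalize per-bin coverage by
the transcript mean, and average transcripts with equal weight; this
binning is the package's own re-specification of the usual
picard-style metric, not a bit-for-bit reproduction.

## The synthetic generator

The generator is first-class, tested code, and its defaults define the
study conditions the tests run under. Each gene carries `n_tss`
alternative first exons (a TSS at each 5' end), alternative internal
exons, and `n_polya` last exons; annotated isoforms are all
full-inclusion (first × last) combinations plus one skip-all isoform,
so alternative exons always have constitutive flanks and annotation
round-trips through GTF and BED12. Inclusion indicators are Bernoulli
draws at per-cell-type probabilities; planted pairs are drawn from the
bivariate Bernoulli with specified marginals and odds ratio, solved in
closed form for the joint cell probabilities (the Plackett
construction) with infeasible triples rejected rather than clipped.
End-site pairs treat site usage as the first Bernoulli variable;
cell-type-constitutive configurations fix an element instead. Noise
processes: per-intron retention, 3'-anchored truncation (poly(dT)
libraries keep 3' ends), unbarcoded and purely intronic contaminant
reads (the latter placed wholly within annotated introns so the
on-target metric can see them), and substitution/insertion/deletion
errors on the 28-mer tag, optionally restricted to the UMI half.

What the generator does *not* emulate: base-level sequence realism
(no quality strings or FASTQ), alignment errors, genomic repeats,
doublets, or empirically calibrated read-depth distributions — the
study only reports median reads per nucleus, so the generator uses a
configurable Poisson mean and makes no claim to match the source
data's depth profile. Passing tests therefore demonstrate the
*correctness of the statistical machinery* under the planted model,
not performance on real tissue.

## Numerical choices and problem sizes

All internal coordinates are 0-based half-open, converted only at
format boundaries (GTF 1-based inclusive; BED 0-based). Every
operation that draws random numbers takes a seed and restores the
caller's RNG state; identical configurations produce byte-identical
fixtures. Ties are always broken deterministically (lexicographic tag
order in the cascade, smaller coordinate for equidistant peaks,
leftmost pair for equal FDR). Zero denominators yield `NA`, never 0.

Test and acceptance problem sizes are chosen to make binomial /
Monte-Carlo error small relative to each assertion while keeping the
default suite fast on a single CPU: ~10⁴ tables for the exhaustive
criterion check, 10⁴ all-null pairs for FDR calibration, 300 planted
pairs at 200 informative UMIs for power, 1,000 exons at 200 reads for
Ψ coverage, and fixtures of a few thousand reads for the end-to-end
model-separation checks.

## Known limitations

* The correction cascade's two unspecified cases are discarded; on
  data with heavy indel noise this is conservative and loses
  molecules (they are counted in the run report).
* The sliding-window matcher is Hamming-based by construction, so a
  single early indel in a tag usually prevents matching; the
  Levenshtein cascade only sees tags that matched.
* Splice-status calls (`unspliced` / `partial` / `full`) are defined
  against annotated introns overlapped by the read span, with a
  retained-intron call requiring ≥ 20 contiguous intronic bases in a
  block; reads overlapping no annotated intron are vacuously `full`.
* `X_tot` counts any ≥ 1 bp span overlap, not only compatible
  overlaps.
* Whether the 50-bp end-site rule is peak-center or peak-interval
  based is ambiguous in the method text; the package measures distance
  to the peak's point position.
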