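# isocoord

Cell-type-resolved exon inclusion and coordination from barcoded
single-nuclei long reads.

Long-read sequencing of barcoded single-nuclei cDNA reports, for each
molecule, the joint configuration of its transcript elements:
alternative internal exons, the transcription start site (TSS) and the
polyadenylation (polyA) site, together with the nucleus of origin.
`isocoord` is an R package for the downstream analysis of such data:
it corrects noisy barcode–UMI tags against a short-read reference,
collapses reads to unique molecules, assigns end sites, quantifies
percent spliced-in (Ψ) per cell type, tests exon pairs and
end-site × exon combinations for coordinated usage, and traces
bulk-level coordination into cell types. It also ships the in silico
priming/fragmentation models used to characterize 3'-tag protocols,
and a synthetic read generator with planted effects for validation.

## The statistics at the core

For an exon with UMI support counts `X_in` (both splice sites
matched), `X_out` (skipped with ≥ 50 aligned bases on both flanks) and
partial counts `X_accIn`, `X_donIn` (one splice site matched, read
ends on the exon):

```
Ψ_overall = (X_in + X_accIn + X_donIn) / (X_in + X_accIn + X_donIn + X_out)
```

A pair of alternative exons is summarized by its 2×2 in/out molecule
table; coordination is tested by Pearson's χ², with effect size the
log-odds ratio `log2[(in·in × out·out) / (in·out × out·in)]` (zero
cells set to 0.5; |log-odds| = 7 is a 128-fold enrichment), and
Benjamini–Yekutieli FDR across pairs. A table is only tested when it
passes the χ² testability criterion — ≥ 80% of cells with expected
count ≥ 5 and all ≥ 1 — otherwise it is classified *constitutive*
(some row/column median expected count < 5: that variable is
effectively fixed) or *low counts*. End-site coupling uses n×2
site × (include, exclude) matrices with ΔΠ (the largest minus the
smallest per-site inclusion fraction) as effect size. The same
machinery, recomputed per cell type with the pseudo-bulk row set
retained, distinguishes genuine within-cell-type coordination from
mixtures of cell-type-constitutive configurations.

## Worked example

Plant an adjacent exon pair coordinated only in excitatory neurons
(odds ratio 16 in EN, independent in astrocytes), generate reads, and
run the full pipeline:

```r
library(isocoord)

psi <- expand.grid(gene_id = "G1", slot = 2:4,
                   celltype = c("EN", "Astro"), stringsAsFactors = FALSE)
psi$psi <- 0.5
cfg <- sim_config(seed = 42, n_genes = 1, exons_per_gene = 5,
                  n_celltypes = 2, celltype_names = c("EN", "Astro"),
                  nuclei_per_celltype = 40, reads_per_nucleus = 40,
                  n_tss = 1, psi_spec = psi,
                  planted_pairs = list(
                    plant_pair("G1", "exon_exon_adjacent", exons = c(2, 3),
                               or_by_celltype = c(EN = 16, Astro = 1))))
sim <- simulate_fixture(cfg)
dir <- tempfile(); write_fixture(sim, dir)
res <- run_pipeline(dir, run_config(seed = 42))

res$pairs[, c("pair_id", "adjacency", "in_in", "in_out", "out_in",
              "out_out", "log_odds", "fdr", "significant")]
#>                        pair_id adjacency in_in in_out out_in out_out log_odds      fdr significant
#>    G1:565-755:+|G1:1100-1254:+  adjacent   703    465    475     783  1.31738 1.28e-27        TRUE
#>    G1:565-755:+|G1:1575-1689:+   distant   520    620    588     639 -0.13376 7.17e-01       FALSE
#>  G1:1100-1254:+|G1:1575-1689:+  adjacent   571    641    590     663  0.00146 1.00e+00       FALSE

res$pair_trace[, c("pair_id", "celltype", "log_odds", "fdr", "class")]
#>                      pair_id celltype log_odds      fdr            class
#>  G1:565-755:+|G1:1100-1254:+    Astro   -0.358 4.37e-02  not_significant
#>  G1:565-755:+|G1:1100-1254:+       EN    3.378 1.53e-72 significant_same
```

The planted pair is the only significant one in pseudo-bulk
(FDR ≈ 10⁻²⁷, log₂-odds 1.3 — diluted by the uncoordinated
astrocytes), and tracing recovers the planted structure: strong
same-direction coordination in EN (log₂-odds 3.4 ≈ the planted
log₂ 16 = 4 after noise), nothing in astrocytes. With default tag
noise (1% substitution), 2,878 of 3,399 planted molecules survive
matching and deduplication, and the run's on-target rate is 0.949.

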