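# Shared fixture builders. Everything is generated in code at test
# time; the small default fixture is memoised per test run.

tiny_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_genes = 2L, exons_per_gene = 5L,
               n_celltypes = 2L, nuclei_per_celltype = 5L,
               reads_per_nucleus = 20, intron_retention_prob = 0,
               contaminant_fracs = c(unbarcoded = 0, intronic = 0),
               tag_error_rates = list(sub = 0, ins = 0, del = 0,
                                      region = "tag"),
               truncation = list(prob = 0, mean = 800, sd = 300))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# A one-gene model handy for hand-built reads: "+" strand, one TSS,
# one polyA, exons at fixed coordinates.
hand_models <- function(exon_starts = c(0L, 500L, 1000L, 1500L),
                        exon_ends = exon_starts + 100L,
                        strand = "+", gene_id = "GX") {
  n <- length(exon_starts)
  ex <- data.frame(exon_id = sprintf("%s:E%d", gene_id, seq_len(n)),
                   gene_id = gene_id, role = c("first", rep("internal", n - 2L), "last"),
                   slot = seq_len(n), variant = 1L, chrom = "chrS",
                   start = exon_starts, end = exon_ends, strand = strand,
                   stringsAsFactors = FALSE)
  txe <- data.frame(transcript_id = paste0(gene_id, ":T1"),
                    exon_id = ex$exon_id, rank = seq_len(n),
                    stringsAsFactors = FALSE)
  structure(list(
    genes = data.frame(gene_id = gene_id, chrom = "chrS",
                       start = min(exon_starts), end = max(exon_ends),
                       strand = strand, n_slots = n, stringsAsFactors = FALSE),
    exons = ex,
    transcripts = data.frame(transcript_id = paste0(gene_id, ":T1"),
                             gene_id = gene_id, stringsAsFactors = FALSE),
    transcript_exons = txe), class = "gene_models")
}

# Build a read table row from a block matrix.
hand_read <- function(id, blocks, strand = "+", gene_id = "GX",
                      chrom = "chrS", celltype = NA_character_) {
  data.frame(read_id = id, chrom = chrom, strand = strand,
             start = blocks[1L, 1L], end = blocks[nrow(blocks), 2L],
             blocks = format_blocks(blocks), gene_id = gene_id,
             celltype = celltype, stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the chi-squared testability
# criterion: literal re-statement of the printed rules with explicit
# loops, kept free of any package internals.
oracle_criterion <- function(M) {
  tot <- sum(M)
  if (tot == 0) return("low_counts")
  E <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M)))
    E[i, j] <- sum(M[i, ]) * sum(M[, j]) / tot
  n_cells <- nrow(M) * ncol(M)
  need <- round(0.8 * n_cells)
  n_ge5 <- 0L
  all_ge1 <- TRUE
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (E[i, j] >= 5) n_ge5 <- n_ge5 + 1L
    if (E[i, j] < 1) all_ge1 <- FALSE
  }
  if (n_ge5 >= need && all_ge1) return("testable")
  for (i in seq_len(nrow(M))) if (median(E[i, ]) < 5) return("constitutive")
  for (j in seq_len(ncol(M))) if (median(E[, j]) < 5) return("constitutive")
  "low_counts"
}
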