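# Exon support counting, percent-spliced-in (PSI) and cell-type
# variability.

# Flattened block table for one gene's reads: fast vectorized exon
# calls. Reads are indexed 1..n in the order given.
build_block_table <- function(reads) {
  bl <- parse_blocks(reads$blocks)
  nb <- vapply(bl, nrow, integer(1))
  b <- do.call(rbind, bl)
  list(n_reads = nrow(reads),
       read_start = reads$start, read_end = reads$end,
       strand = reads$strand,
       blocks = data.frame(read = rep(seq_len(nrow(reads)), nb),
                           start = b[, 1L], end = b[, 2L],
                           rank = unlist(lapply(nb, seq_len), use.names = FALSE),
                           nblocks = rep(nb, nb)))
}

# rowsum over reads, returned as a length-n vector in read order.
rowsum_reads <- function(x, read, n) {
  out <- numeric(n)
  rs <- rowsum(as.numeric(x), read)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Per-read support calls for one exon
#'
#' Classifies each read of the exon's gene into one of: `in` (an
#' internal block matches both splice sites exactly), `acc_in` /
#' `don_in` (a terminal block matches the acceptor / donor splice site
#' and the read ends on the exon), `out` (no block overlaps the exon
#' and at least `flank` aligned bases flank it on both sides),
#' `tot_only` (the read span overlaps the exon without an informative
#' call) or `none`. Splice-site identity is exact -- no fuzz window.
#'
#' @param exon List or one-row data frame with `start`, `end`,
#'   `strand` (0-based half-open).
#' @param bt Block table from `build_block_table()` for the gene's
#'   reads.
#' @param flank Minimum aligned bases on both sides for a skip call
#'   (default 50).
#' @return Character vector, one call per read.
#' @export
exon_calls <- function(exon, bt, flank = 50L) {
  es <- exon$start; ee <- exon$end
  n <- bt$n_reads
  b <- bt$blocks
  full <- b$start == es & b$end == ee & b$rank > 1L & b$rank < b$nblocks
  leftp <- b$start == es & b$end <= ee & b$rank == b$nblocks & b$rank > 1L & !full
  rightp <- b$end == ee & b$start >= es & b$rank == 1L & b$nblocks > 1L & !full
  ovb <- b$start < ee & b$end > es
  left_bases <- pmax(0L, pmin(b$end, es) - b$start)
  right_bases <- pmax(0L, b$end - pmax(b$start, ee))
  has_full <- rowsum_reads(full, b$read, n) > 0
  has_left <- rowsum_reads(leftp, b$read, n) > 0
  has_right <- rowsum_reads(rightp, b$read, n) > 0
  any_ovb <- rowsum_reads(ovb, b$read, n) > 0
  lb <- rowsum_reads(left_bases, b$read, n)
  rb <- rowsum_reads(right_bases, b$read, n)
  ov_span <- bt$read_start < ee & bt$read_end > es
  skip <- !any_ovb & lb >= flank & rb >= flank
  # strand maps genomic left/right to acceptor/donor
  left_lab <- ifelse(bt$strand == "+", "acc_in", "don_in")
  right_lab <- ifelse(bt$strand == "+", "don_in", "acc_in")
  out <- rep("none", n)
  out[ov_span] <- "tot_only"
  out[skip] <- "out"
  out[has_right] <- right_lab[has_right]
  out[has_left] <- left_lab[has_left]
  out[has_full] <- "in"
  out
}

#' Count UMI support for an exon
#'
#' Produces the five support counts for one exon over a set of
#' deduplicated molecules of its gene: `X_in` (both splice sites
#' matched), `X_out` (skipped with >= `flank` aligned bases on both
#' sides), `X_acc_in` / `X_don_in` (one splice site matched, read ends
#' on the exon), and `X_tot` (read span overlaps the exon by >= 1 bp;
#' this includes skipping and intron-retaining molecules).
#'
#' @inheritParams exon_calls
#' @param molecules Deduplicated read table for the exon's gene (used
#'   when `bt` not supplied).
#' @param bt Optional precomputed block table.
#' @return Named integer vector
#'   `c(X_in, X_out, X_acc_in, X_don_in, X_tot)`.
#' @export
count_exon_support <- function(exon, molecules = NULL, bt = NULL,
                               flank = 50L) {
  if (is.null(bt)) bt <- build_block_table(molecules)
  calls <- exon_calls(exon, bt, flank)
  c(X_in = sum(calls == "in"), X_out = sum(calls == "out"),
    X_acc_in = sum(calls == "acc_in"), X_don_in = sum(calls == "don_in"),
    X_tot = sum(calls != "none"))
}

#' The three percent-spliced-in values
#'
#' `psi_overall = (X_in + X_acc_in + X_don_in) / (X_in + X_acc_in +
#' X_don_in + X_out)`; `psi_acceptor` and `psi_donor` drop the
#' opposite-side partial count. `NA` where a denominator is zero.
#'
#' @param support Named counts from [count_exon_support()].
#' @return Named numeric vector
#'   `c(psi_overall, psi_acceptor, psi_donor)`.
#' @export
compute_psi <- function(support) {
  s <- as.list(support)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  inc <- s$X_in + s$X_acc_in + s$X_don_in
  c(psi_overall = ratio(inc, inc + s$X_out),
    psi_acceptor = ratio(s$X_in + s$X_acc_in,
                         s$X_in + s$X_acc_in + s$X_out),
    psi_donor = ratio(s$X_in + s$X_don_in,
                      s$X_in + s$X_don_in + s$X_out))
}

#' Discover internal exons from read block chains
#'
#' An internal exon is a block flanked by splice junctions on both
#' sides, i.e. neither the first nor the last block of its read. Each
#' distinct `(chrom, start, end, strand)` observed as internal in at
#' least one read defines one exon; annotation status and the number
#' of annotated splice sites are attached, along with the count of
#' bases not covered by any annotated exon (used by the intron
#' retention / alternative-site exclusion rule).
#'
#' @param molecules Deduplicated read table.
#' @param models Gene models.
#' @return Data frame of exons with `exon_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `length`, `n_internal_reads`,
#'   `annotated`, `n_annot_sites`, `nonexonic_bases`, `novel`,
#'   `microexon`.
#' @export
discover_internal_exons <- function(molecules, models) {
  bl <- parse_blocks(molecules$blocks)
  nb <- vapply(bl, nrow, integer(1))
  b <- do.call(rbind, bl)
  rank <- unlist(lapply(nb, seq_len), use.names = FALSE)
  internal <- rank > 1L & rank < rep(nb, nb)
  ridx <- rep(seq_len(nrow(molecules)), nb)[internal]
  d <- data.frame(gene_id = molecules$gene_id[ridx],
                  chrom = molecules$chrom[ridx],
                  start = b[internal, 1L], end = b[internal, 2L],
                  strand = molecules$strand[ridx],
                  stringsAsFactors = FALSE)
  key <- paste(d$gene_id, d$chrom, d$start, d$end, d$strand)
  cnt <- table(key)
  ex <- d[!duplicated(key), , drop = FALSE]
  ex$n_internal_reads <- as.integer(cnt[paste(ex$gene_id, ex$chrom, ex$start,
                                              ex$end, ex$strand)])
  ex$length <- ex$end - ex$start
  ann <- models$exons
  akey <- paste(ann$gene_id, ann$chrom, ann$start, ann$end, ann$strand)
  ex$annotated <- paste(ex$gene_id, ex$chrom, ex$start, ex$end,
                        ex$strand) %in% akey
  # annotated splice sites and non-exonic base counts, per gene
  ex$n_annot_sites <- 0L
  ex$nonexonic_bases <- ex$length
  for (gid in unique(ex$gene_id)) {
    ae <- ann[ann$gene_id == gid, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(ae$start + 1L, ae$end))
    idx <- which(ex$gene_id == gid)
    ex$n_annot_sites[idx] <- (ex$start[idx] %in% ae$start) +
      (ex$end[idx] %in% ae$end)
    qr <- IRanges::IRanges(ex$start[idx] + 1L, ex$end[idx])
    covered <- integer(length(idx))
    hits <- IRanges::findOverlaps(qr, ir)
    if (length(hits)) {
      w <- IRanges::width(IRanges::pintersect(qr[S4Vectors::queryHits(hits)],
                                              ir[S4Vectors::subjectHits(hits)]))
      agg <- rowsum(w, S4Vectors::queryHits(hits))
      covered[as.integer(rownames(agg))] <- agg[, 1L]
    }
    ex$nonexonic_bases[idx] <- ex$length[idx] - covered
  }
  ex$novel <- !ex$annotated
  ex$microexon <- ex$length <= 27L
  ex$exon_id <- sprintf("%s:%d-%d:%s", ex$gene_id, ex$start, ex$end, ex$strand)
  rownames(ex) <- NULL
  ex[, c("exon_id", "gene_id", "chrom", "start", "end", "strand", "length",
         "n_internal_reads", "annotated", "n_annot_sites", "nonexonic_bases",
         "novel", "microexon")]
}

#' Support and PSI table for a set of exons
#'
#' Computes [count_exon_support()] and [compute_psi()] for every exon
#' in every requested context (pseudo-bulk plus each cell type present
#' in `molecules$celltype`).
#'
#' @param exons Exon data frame (from [discover_internal_exons()]).
#' @param molecules Deduplicated read table with a `celltype` column
#'   (may be NA).
#' @param contexts Character vector of contexts; default pseudo-bulk
#'   plus all cell types.
#' @param flank Skip-call flank (bp).
#' @return Long data frame: one row per exon per context with the five
#'   counts and three PSI values.
#' @export
psi_table <- function(exons, molecules, contexts = NULL, flank = 50L) {
  cts <- sort(unique(molecules$celltype[!is.na(molecules$celltype)]))
  if (is.null(contexts)) contexts <- c("pseudo_bulk", cts)
  out <- list()
  for (gid in unique(exons$gene_id)) {
    gex <- exons[exons$gene_id == gid, , drop = FALSE]
    gm <- molecules[molecules$gene_id == gid, , drop = FALSE]
    for (ctx in contexts) {
      sub <- if (ctx == "pseudo_bulk") gm
      else gm[!is.na(gm$celltype) & gm$celltype == ctx, , drop = FALSE]
      if (nrow(sub) == 0L) {
        z <- data.frame(exon_id = gex$exon_id, context = ctx, X_in = 0L,
                        X_out = 0L, X_acc_in = 0L, X_don_in = 0L, X_tot = 0L,
                        psi_overall = NA_real_, psi_acceptor = NA_real_,
                        psi_donor = NA_real_, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- z
        next
      }
      bt <- build_block_table(sub)
      rows <- lapply(seq_len(nrow(gex)), function(i) {
        sup <- count_exon_support(gex[i, ], bt = bt, flank = flank)
        psi <- compute_psi(sup)
        data.frame(exon_id = gex$exon_id[i], context = ctx,
                   as.list(sup), as.list(psi), stringsAsFactors = FALSE)
      })
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Alternative-exon filter
#'
#' Retains exons whose pseudo-bulk support satisfies all of:
#' `0.05 <= psi <= 0.95` for all three PSI variants (boundary
#' inclusive), coverage
#' `(X_in + X_acc_in + X_don_in + X_out) / X_tot >= 0.8`, and that are
#' not excluded as intron-retention / alternative-site events
#' (non-annotated exons with one or two annotated splice sites and
#' >= 70 non-exonic bases).
#'
#' @param psi_bulk Pseudo-bulk rows of [psi_table()] merged with the
#'   exon columns of [discover_internal_exons()].
#' @param psi_window Inclusive PSI window (default `c(0.05, 0.95)`).
#' @param min_coverage Coverage-ratio threshold (default 0.8).
#' @param novel_nonexonic Non-exonic base threshold (default 70).
#' @return The retained rows, with a `retained_reason` attribute-free
#'   logical breakdown in columns `pass_psi`, `pass_coverage`,
#'   `pass_novel_rule`.
#' @export
filter_alternative_exons <- function(psi_bulk, psi_window = c(0.05, 0.95),
                                     min_coverage = 0.8,
                                     novel_nonexonic = 70L) {
  p <- psi_bulk
  pass_psi <- !is.na(p$psi_overall) & !is.na(p$psi_acceptor) &
    !is.na(p$psi_donor) &
    p$psi_overall >= psi_window[1L] & p$psi_overall <= psi_window[2L] &
    p$psi_acceptor >= psi_window[1L] & p$psi_acceptor <= psi_window[2L] &
    p$psi_donor >= psi_window[1L] & p$psi_donor <= psi_window[2L]
  informative <- p$X_in + p$X_acc_in + p$X_don_in + p$X_out
  pass_cov <- p$X_tot > 0 & informative / p$X_tot >= min_coverage
  excl_ir <- !p$annotated & p$n_annot_sites >= 1L &
    p$nonexonic_bases >= novel_nonexonic
  p$pass_psi <- pass_psi
  p$pass_coverage <- pass_cov
  p$pass_novel_rule <- !excl_ir
  out <- p[pass_psi & pass_cov & !excl_ir, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cell-type PSI with the depth rule
#'
#' `psi_overall` per cell type, set to `NA` unless `X_tot >= min_tot`
#' for the exon in that cell type.
#'
#' @param psi_long Output of [psi_table()].
#' @param min_tot Per-cell-type depth threshold (default 10).
#' @return Wide data frame: one row per exon, one PSI column per cell
#'   type.
#' @export
celltype_psi <- function(psi_long, min_tot = 10L) {
  ct <- psi_long[psi_long$context != "pseudo_bulk", , drop = FALSE]
  ct$psi <- ifelse(ct$X_tot >= min_tot, ct$psi_overall, NA_real_)
  wide <- stats::reshape(ct[, c("exon_id", "context", "psi")],
                         idvar = "exon_id", timevar = "context",
                         direction = "wide")
  names(wide) <- sub("^psi\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Cell-type variability of exon inclusion
#'
#' Variability is `max(psi) - min(psi)` over non-NA cell-type values
#' (at least `min_celltypes` required), categorized at the 0.25 / 0.75
#' cuts: `low` (<= 0.25), `mid`, `high` (> 0.75).
#'
#' @param psi_wide Output of [celltype_psi()]: `exon_id` plus one
#'   column per cell type.
#' @param min_celltypes Minimum non-NA cell types (default 2).
#' @param cuts Category cuts (default `c(0.25, 0.75)`).
#' @return Data frame `exon_id`, `n_celltypes`, `variability`,
#'   `category` (NA rows where too few cell types).
#' @export
psi_variability <- function(psi_wide, min_celltypes = 2L,
                            cuts = c(0.25, 0.75)) {
  m <- as.matrix(psi_wide[, setdiff(names(psi_wide), "exon_id"),
                          drop = FALSE])
  nn <- rowSums(!is.na(m))
  v <- ifelse(nn >= min_celltypes,
              apply(m, 1L, max, na.rm = TRUE) -
                apply(m, 1L, min, na.rm = TRUE), NA_real_)
  cat <- ifelse(is.na(v), NA_character_,
                ifelse(v <= cuts[1L], "low",
                       ifelse(v <= cuts[2L], "mid", "high")))
  data.frame(exon_id = psi_wide$exon_id, n_celltypes = nn,
             variability = v, category = cat, stringsAsFactors = FALSE)
}

#' Quadrant labels for novel exons
#'
#' Places each exon at (pseudo-bulk PSI, cell-type variability) and
#' labels the four quadrants cut at (0.5, 0.5); both boundaries are
#' inclusive upward (a value of exactly 0.5 counts as high).
#'
#' @param psi_bulk Numeric vector of pseudo-bulk PSI values.
#' @param variability Matching variability values.
#' @param cut Quadrant cut (default 0.5 on both axes).
#' @return Character vector like `"high_inclusion/low_variability"`.
#' @export
novel_exon_quadrants <- function(psi_bulk, variability, cut = 0.5) {
  inc <- ifelse(psi_bulk >= cut, "high_inclusion", "low_inclusion")
  var <- ifelse(variability >= cut, "high_variability", "low_variability")
  ifelse(is.na(psi_bulk) | is.na(variability), NA_character_,
         paste(inc, var, sep = "/"))
}

#' Compare disease-associated exon variability
#'
#' Two-sided Wilcoxon rank-sum test between the variability of
#' disease-associated and all other alternative exons (exact when both
#' groups have <= 25 observations and no ties; normal approximation
#' with tie correction otherwise), plus the ratio of group medians.
#' Microexons (length <= 27 bp) can be excluded.
#'
#' @param variability Numeric variability values.
#' @param is_disease Logical membership flags, same length.
#' @param exon_length Optional exon lengths, required when
#'   `exclude_microexons = TRUE`.
#' @param exclude_microexons Drop exons `<= microexon_max` nt first.
#' @param microexon_max Microexon length cutoff (default 27).
#' @return List with `p_value`, `fold_ratio`
#'   (`median(disease)/median(other)`, NA when the other median is 0),
#'   `n_disease`, `n_other`.
#' @export
compare_disease_exons <- function(variability, is_disease,
                                  exon_length = NULL,
                                  exclude_microexons = FALSE,
                                  microexon_max = 27L) {
  keep <- !is.na(variability) & !is.na(is_disease)
  if (exclude_microexons) {
    stopifnot(!is.null(exon_length))
    keep <- keep & exon_length > microexon_max
  }
  x <- variability[keep & is_disease]
  y <- variability[keep & !is_disease]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- length(x) <= 25L && length(y) <= 25L
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = FALSE))
  med_y <- stats::median(y)
  list(p_value = wt$p.value,
       fold_ratio = if (med_y == 0) NA_real_ else stats::median(x) / med_y,
       n_disease = length(x), n_other = length(y))
}

#' Per-gene expression variability across cell types
#'
#' Max minus min of (log-scale) expression across cell types, NA cell
#' types ignored; genes absent from the table give NA.
#'
#' @param expression Matrix or data frame, genes x cell types, of
#'   log-normalized expression (e.g. log10(TPM + 1)).
#' @param genes Gene ids to report (default all rows).
#' @return Named numeric vector of variabilities.
#' @export
gene_expression_variability <- function(expression, genes = rownames(expression)) {
  m <- as.matrix(expression)
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  present <- genes[genes %in% rownames(m)]
  v <- apply(m[present, , drop = FALSE], 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else max(x) - min(x)
  })
  out[present] <- v
  out
}

#' Transcripts-per-million and its log transform
#'
#' `tpm = count / sum(count) * 1e6` (no length normalization;
#' end-anchored chemistry), and `log10(tpm + 1)` for correlation
#' reports.
#'
#' @param counts Named numeric vector of per-gene molecule counts.
#' @return `tpm()`: numeric vector; `log_tpm()`: `log10(tpm + 1)`.
#' @export
tpm <- function(counts) counts / sum(counts) * 1e6

#' @rdname tpm
#' @export
log_tpm <- function(counts) log10(tpm(counts) + 1)
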