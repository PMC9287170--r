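# End-site assignment and per-read quality metrics.

# 5' and 3' genomic end positions of reads (0-based half-open spans).
read_ends <- function(reads) {
  plus <- reads$strand == "+"
  list(five = ifelse(plus, reads$start, reads$end),
       three = ifelse(plus, reads$end, reads$start))
}

# Nearest same-strand peak within `window` bp of each position.
# Ties go to the smaller-coordinate peak. Returns site ids (NA if none).
nearest_peak <- function(chrom, pos, strand, peaks, window, stranded = TRUE) {
  out <- rep(NA_character_, length(pos))
  n_ties <- 0L
  for (i in seq_along(pos)) {
    p <- peaks[peaks$chrom == chrom[i], , drop = FALSE]
    if (stranded) p <- p[p$strand == strand[i], , drop = FALSE]
    if (!nrow(p)) next
    d <- abs(p$pos - pos[i])
    ok <- d <= window
    if (!any(ok)) next
    dmin <- min(d[ok])
    cands <- which(ok & d == dmin)
    if (length(cands) > 1L) n_ties <- n_ties + 1L
    out[i] <- p$site_id[cands[which.min(p$pos[cands])]]
  }
  structure(out, n_ties = n_ties)
}

#' Assign TSS and polyA sites to read ends
#'
#' Each read's 5' end (strand-resolved) is matched to the closest
#' same-strand TSS peak within `window` bp, and its 3' end to the
#' closest polyA peak, boundary inclusive. Equidistant peaks resolve
#' to the smaller coordinate (deterministic, counted).
#'
#' @param reads Read table with `chrom`, `strand`, `start`, `end`.
#' @param tss,polya Peak data frames from [read_peaks()] (columns
#'   `site_id`, `chrom`, `pos`, `strand`).
#' @param window Maximum distance in bp (default 50).
#' @param stranded Require matching strand (set `FALSE` for unstranded
#'   peak files).
#' @return `reads` with `tss_id` and `polya_id` columns (NA when no
#'   peak qualifies).
#' @export
assign_end_sites <- function(reads, tss, polya, window = 50L,
                             stranded = TRUE) {
  e <- read_ends(reads)
  reads$tss_id <- as.character(nearest_peak(reads$chrom, e$five, reads$strand,
                                            tss, window, stranded))
  reads$polya_id <- as.character(nearest_peak(reads$chrom, e$three,
                                              reads$strand, polya, window,
                                              stranded))
  reads
}

#' Classify 5'/3' completeness of reads
#'
#' A read end is complete when it lies within `window` bp of a
#' published CAGE (5') or polyA (3') peak.
#'
#' @inheritParams assign_end_sites
#' @param cage CAGE/TSS peak data frame.
#' @return `reads` with logical `five_prime_complete` and
#'   `three_prime_complete` columns.
#' @export
classify_completeness <- function(reads, cage, polya, window = 50L,
                                  stranded = TRUE) {
  e <- read_ends(reads)
  reads$five_prime_complete <-
    !is.na(nearest_peak(reads$chrom, e$five, reads$strand, cage, window,
                        stranded))
  reads$three_prime_complete <-
    !is.na(nearest_peak(reads$chrom, e$three, reads$strand, polya, window,
                        stranded))
  reads
}

#' On-target rate of a read set
#'
#' Fraction of reads with at least 1 bp of block overlap with any
#' annotated exon.
#'
#' @param reads Read table with a `blocks` column.
#' @param exons Annotated exon data frame (`chrom`, `start`, `end`).
#' @return Fraction in `[0, 1]`.
#' @export
on_target_rate <- function(reads, exons) {
  if (nrow(reads) == 0L) stop("on-target rate undefined for zero reads")
  bl <- parse_blocks(reads$blocks)
  nb <- vapply(bl, nrow, integer(1))
  b <- do.call(rbind, bl)
  gr_b <- GenomicRanges::GRanges(rep(reads$chrom, nb),
                                 IRanges::IRanges(b[, 1L] + 1L, b[, 2L]))
  gr_e <- GenomicRanges::GRanges(exons$chrom,
                                 IRanges::IRanges(exons$start + 1L, exons$end))
  hit <- IRanges::overlapsAny(gr_b, gr_e)
  mean(vapply(split(hit, rep(seq_len(nrow(reads)), nb)), any, logical(1)))
}

#' Per-read exon ratio
#'
#' The expected exon count of a gene is the mean over its annotated
#' transcripts; each read's observed block count is divided by it.
#'
#' @param reads Read table with `gene_id` and `blocks`.
#' @param models Gene models ([read_annotation()] /
#'   [generate_gene_models()]).
#' @return Numeric vector of ratios (`NA` for genes absent from the
#'   annotation).
#' @export
exon_ratio <- function(reads, models) {
  txg <- models$transcripts
  cnt <- table(models$transcript_exons$transcript_id)
  per_tx <- as.numeric(cnt[txg$transcript_id])
  expected <- tapply(per_tx, txg$gene_id, mean)
  obs <- vapply(parse_blocks(reads$blocks), nrow, integer(1))
  as.numeric(obs / expected[reads$gene_id])
}

# Unique annotated introns per gene: gaps between consecutive exon
# ranks within each transcript.
gene_introns <- function(models) {
  txe <- merge(models$transcript_exons, models$exons, by = "exon_id")
  out <- lapply(split(txe, txe$transcript_id), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2L) return(NULL)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = e$end[-nrow(e)], end = e$start[-1L],
               strand = e$strand[1L], stringsAsFactors = FALSE)
  })
  ii <- do.call(rbind, out)
  ii <- ii[ii$end > ii$start, , drop = FALSE]
  unique(ii)
}

#' Splice status of reads
#'
#' Against the annotated introns of the read's gene:
#' `unspliced` -- no overlapped intron is removed; `full` -- every
#' annotated intron overlapped by the read span is removed; `partial`
#' -- otherwise. An intron counts as retained when a read block covers
#' at least `min_retained` contiguous intronic bases (tolerance for
#' alignment wobble); reads overlapping no annotated intron are
#' vacuously `full`.
#'
#' @param reads Read table with `gene_id`, `start`, `end`, `blocks`.
#' @param models Gene models.
#' @param min_retained Minimum contiguous intronic bases for a
#'   retained-intron call (default 20).
#' @return Character vector in `{"unspliced", "partial", "full"}`.
#' @export
splice_status <- function(reads, models, min_retained = 20L) {
  introns <- gene_introns(models)
  ibg <- split(introns, introns$gene_id)
  bl <- parse_blocks(reads$blocks)
  vapply(seq_len(nrow(reads)), function(i) {
    ii <- ibg[[reads$gene_id[i]]]
    b <- bl[[i]]
    if (is.null(ii) || nrow(ii) == 0L) return("full")
    ov <- ii$start < reads$end[i] & ii$end > reads$start[i]
    if (!any(ov)) return("full")
    ii <- ii[ov, , drop = FALSE]
    retained <- vapply(seq_len(nrow(ii)), function(j) {
      inside <- pmin(b[, 2L], ii$end[j]) - pmax(b[, 1L], ii$start[j])
      any(inside >= min_retained)
    }, logical(1))
    if (all(retained)) "unspliced"
    else if (any(retained)) "partial"
    else "full"
  }, character(1))
}

#' Saturation curve: unique molecules per sampled read
#'
#' Seeded subsampling without replacement at each depth; reports the
#' number of distinct `(barcode, UMI, gene)` molecules divided by the
#' sampled read count (one UMI per so-many barcoded reads).
#'
#' @param records Barcoded read table with `barcode`, `umi`, `gene_id`.
#' @param depths Integer vector of depths, each `<=` the record count.
#' @param seed Integer seed.
#' @return Data frame with `depth` and `umis_per_read`.
#' @export
saturation_curve <- function(records, depths, seed) {
  if (any(depths > nrow(records))) stop("depth exceeds total reads")
  key <- paste(records$barcode, records$umi, records$gene_id)
  ratios <- with_seed(seed, vapply(depths, function(d) {
    idx <- sample.int(length(key), d)
    length(unique(key[idx])) / d
  }, numeric(1)))
  data.frame(depth = depths, umis_per_read = ratios)
}
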