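# Annotation and read-table I/O. Internal coordinates are 0-based
# half-open everywhere; conversion happens only at format boundaries
# (GTF is 1-based inclusive, BED 0-based half-open).

#' Write gene models as GTF
#'
#' Emits gene, transcript and exon features with `gene_id` /
#' `transcript_id` attributes, 1-based inclusive coordinates.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  ex <- merge(models$transcript_exons, models$exons, by = "exon_id")
  ex <- merge(ex, models$transcripts, by = "transcript_id",
              suffixes = c("", ".tx"))
  ex <- ex[order(ex$transcript_id, ex$rank), ]
  lines <- c(
    with(models$genes, sprintf(
      'chrS\tisocoord\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
      start + 1L, end, strand, gene_id)),
    vapply(split(ex, ex$transcript_id), function(e) sprintf(
      'chrS\tisocoord\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      min(e$start) + 1L, max(e$end), e$strand[1L], e$gene_id[1L],
      e$transcript_id[1L]), character(1)),
    sprintf('chrS\tisocoord\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_id "%s";',
            ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
            ex$exon_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as BED12
#'
#' One line per transcript, blocks = exons, 0-based half-open.
#'
#' @inheritParams write_gtf
#' @export
write_bed12 <- function(models, path) {
  ex <- merge(models$transcript_exons, models$exons, by = "exon_id")
  lines <- vapply(split(ex, ex$transcript_id), function(e) {
    e <- e[order(e$start), ]
    s <- min(e$start); en <- max(e$end)
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            e$chrom[1L], s, en, e$transcript_id[1L], e$strand[1L], s, en,
            nrow(e),
            paste0(paste(e$end - e$start, collapse = ","), ","),
            paste0(paste(e$start - s, collapse = ","), ","))
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

# Write end-site peaks (1-nt features) as BED6.
write_bed6_peaks <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", peaks$chrom, peaks$pos,
                     peaks$pos + 1L, peaks$site_id, peaks$strand), path)
  invisible(path)
}

#' Read end-site peaks from BED6
#'
#' @param path BED file (0-based half-open; column 6 strand).
#' @param kind `"TSS"` or `"polyA"` label attached to the peaks.
#' @return Data frame with `site_id`, `chrom`, `pos`, `strand`, `kind`,
#'   sorted by (chrom, pos). Point position is the feature start.
#' @export
read_peaks <- function(path, kind = c("TSS", "polyA")) {
  kind <- match.arg(kind)
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(site_id = gr$name,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    pos = GenomicRanges::start(gr) - 1L,
                    strand = as.character(GenomicRanges::strand(gr)),
                    kind = kind, stringsAsFactors = FALSE)
  if (anyDuplicated(out$site_id)) stop("peak ids must be unique: ", path)
  out[order(out$chrom, out$pos), ]
}

#' Read gene annotation (GTF or BED12) into gene models
#'
#' GTF is parsed with rtracklayer (1-based inclusive, attributes
#' `gene_id` / `transcript_id`); BED12 blocks are taken as exons. The
#' result uses the package's internal 0-based half-open convention.
#' Overlapping exons within one transcript are rejected.
#'
#' @param path Annotation file; format from the extension
#'   (`.gtf` / `.bed`).
#' @return A `gene_models`-shaped list (`genes`, `exons`,
#'   `transcripts`, `transcript_exons`).
#' @export
read_annotation <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    df <- data.frame(exon_id = ex$exon_id %||% NA_character_,
                     gene_id = ex$gene_id,
                     transcript_id = ex$transcript_id,
                     chrom = as.character(GenomicRanges::seqnames(ex)),
                     start = GenomicRanges::start(ex) - 1L,
                     end = GenomicRanges::end(ex),
                     strand = as.character(GenomicRanges::strand(ex)),
                     stringsAsFactors = FALSE)
  } else if (fmt %in% c("bed", "bed12")) {
    gr <- rtracklayer::import(path, format = "bed")
    rows <- lapply(seq_along(gr), function(i) {
      bl <- gr$blocks[[i]]
      s0 <- GenomicRanges::start(gr)[i] - 1L
      data.frame(exon_id = NA_character_,
                 gene_id = sub(":T[0-9]+$", "", gr$name[i]),
                 transcript_id = gr$name[i],
                 chrom = as.character(GenomicRanges::seqnames(gr))[i],
                 start = s0 + IRanges::start(bl) - 1L,
                 end = s0 + IRanges::end(bl),
                 strand = as.character(GenomicRanges::strand(gr))[i],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else stop("unsupported annotation format: ", path)
  # validate per transcript: sorted, non-overlapping
  for (tid in unique(df$transcript_id)) {
    e <- df[df$transcript_id == tid, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$end[-nrow(e)] > e$start[-1L]))
      stop("overlapping exons within transcript ", tid)
  }
  key <- paste(df$chrom, df$start, df$end, df$strand, df$gene_id)
  uex <- df[!duplicated(key), ]
  uex$exon_id <- ifelse(is.na(uex$exon_id),
                        sprintf("%s:%d-%d", uex$gene_id, uex$start, uex$end),
                        uex$exon_id)
  df$exon_id <- uex$exon_id[match(key, paste(uex$chrom, uex$start, uex$end,
                                             uex$strand, uex$gene_id))]
  genes <- do.call(rbind, lapply(split(df, df$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               start = min(e$start), end = max(e$end),
               strand = e$strand[1L], stringsAsFactors = FALSE)))
  rownames(genes) <- NULL
  tx <- unique(df[, c("transcript_id", "gene_id")])
  rownames(tx) <- NULL
  txe <- do.call(rbind, lapply(split(df, df$transcript_id), function(e) {
    e <- if (e$strand[1L] == "+") e[order(e$start), ] else e[order(-e$start), ]
    data.frame(transcript_id = e$transcript_id, exon_id = e$exon_id,
               rank = seq_len(nrow(e)), stringsAsFactors = FALSE)
  }))
  rownames(txe) <- NULL
  exons <- uex[order(uex$gene_id, uex$start),
               c("exon_id", "gene_id", "chrom", "start", "end", "strand")]
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons, transcripts = tx,
                 transcript_exons = txe), class = "gene_models")
}

#' Read or write the pipeline read table
#'
#' The TSV dialect carries one aligned (optionally deduplicated)
#' long-read molecule per row: `read_id`, `barcode`, `umi`, `celltype`,
#' `gene_id`, `chrom`, `strand`, `start`, `end`, `blocks`
#' (comma-separated `start-end`, 0-based half-open), `tss_id`,
#' `polya_id`. `"NA"` marks missing values. Rows whose blocks fall
#' outside the read span or are malformed are rejected with a count.
#'
#' @param path TSV path.
#' @param reads Data frame to write.
#' @return `read_read_table()`: the validated data frame (rejected row
#'   count in attribute `n_rejected`); `write_read_table()`: `path`.
#' @export
read_read_table <- function(path) {
  df <- read_tsv(path)
  need <- c("read_id", "chrom", "strand", "start", "end", "blocks", "gene_id")
  if (!all(need %in% names(df)))
    stop("read table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    b <- tryCatch(parse_blocks(df$blocks[i])[[1L]], error = function(e) NULL)
    ok[i] <- !is.null(b) && valid_blocks(b) &&
      b[1L, 1L] >= df$start[i] && b[nrow(b), 2L] <= df$end[i]
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' @rdname read_read_table
#' @export
write_read_table <- function(reads, path) write_tsv(reads, path)

#' Write a complete synthetic fixture to disk
#'
#' Writes annotation (GTF and BED12), the read table, tag sequences,
#' TSS and polyA peak BEDs, barcode whitelist, barcode-to-cell-type
#' map, the short-read (Illumina) tag reference, the ground-truth
#' molecule and linkage tables and true inclusion probabilities.
#' Re-reading with [read_fixture()] reproduces the tables exactly.
#'
#' @param sim A [simulate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  fp <- function(x) file.path(dir, x)
  write_gtf(sim$models, fp("annotation.gtf"))
  write_bed12(sim$models, fp("annotation.bed12.bed"))
  write_bed6_peaks(sim$models$tss, fp("tss_peaks.bed"))
  write_bed6_peaks(sim$models$polya, fp("polya_peaks.bed"))
  write_tsv(sim$emitted$reads, fp("reads.tsv"))
  write_tsv(sim$emitted$tags, fp("tags.tsv"))
  write_tsv(sim$emitted$celltype_map, fp("celltypes.tsv"))
  write_tsv(sim$emitted$illumina_tags, fp("illumina_tags.tsv"))
  write_tsv(sim$truth$molecules, fp("truth_molecules.tsv"))
  write_tsv(sim$emitted$link, fp("truth_link.tsv"))
  write_tsv(sim$truth$psi_true, fp("psi_true.tsv"))
  writeLines(sim$emitted$whitelist, fp("whitelist.txt"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  fp <- function(x) file.path(dir, x)
  list(models = read_annotation(fp("annotation.gtf")),
       tss = read_peaks(fp("tss_peaks.bed"), "TSS"),
       polya = read_peaks(fp("polya_peaks.bed"), "polyA"),
       reads = read_read_table(fp("reads.tsv")),
       tags = read_tsv(fp("tags.tsv")),
       celltype_map = read_tsv(fp("celltypes.tsv")),
       illumina_tags = read_tsv(fp("illumina_tags.tsv")),
       truth_molecules = read_tsv(fp("truth_molecules.tsv")),
       truth_link = read_tsv(fp("truth_link.tsv")),
       psi_true = read_tsv(fp("psi_true.tsv")),
       whitelist = readLines(fp("whitelist.txt")))
}

#' Seeded uniform subsampling without replacement
#'
#' @param records Data frame.
#' @param n Number of rows to keep (`n <= nrow(records)`).
#' @param seed Integer seed.
#' @return The sampled rows, in original order (order-independent set).
#' @export
subsample_records <- function(records, n, seed) {
  if (n > nrow(records)) stop("subsample size exceeds record count")
  idx <- with_seed(seed, sample.int(nrow(records), n))
  records[sort(idx), , drop = FALSE]
}
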