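# Read emission: molecule -> aligned read with intron retention,
# 3'-anchored truncation, contaminant classes and tag corruption.

# Corrupt a DNA string with per-base substitution/insertion/deletion
# probabilities; region = "umi" restricts errors to the last 12 nt.
corrupt_tag <- function(tag, rates) {
  chars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  editable <- if ((rates$region %||% "tag") == "umi")
    seq.int(n - 11L, n) else seq_len(n)
  out <- character(0)
  for (i in seq_len(n)) {
    c_i <- chars[i]
    if (i %in% editable) {
      u <- stats::runif(1L)
      if (u < rates$del) next
      if (u < rates$del + rates$sub) c_i <- sample(setdiff(DNA, c_i), 1L)
      if (u >= 1 - rates$ins) c_i <- paste0(c_i, sample(DNA, 1L))
    }
    out <- c(out, c_i)
  }
  paste0(out, collapse = "")
}

# Blocks (genomic, sorted) for a molecule's chain of exon rows, with
# per-gap intron retention (a retained intron merges its two flanks).
chain_to_blocks <- function(ex, retention_prob) {
  b <- cbind(start = ex$start, end = ex$end)
  b <- b[order(b[, 1L]), , drop = FALSE]
  n <- nrow(b)
  if (n > 1L && retention_prob > 0) {
    retain <- stats::runif(n - 1L) < retention_prob
    out <- list(b[1L, ])
    for (i in 2L:n) {
      if (retain[i - 1L]) out[[length(out)]][2L] <- b[i, 2L]
      else out[[length(out) + 1L]] <- b[i, ]
    }
    b <- do.call(rbind, out)
    colnames(b) <- c("start", "end")
  }
  b
}

# Keep the 3'-most `len` transcribed nucleotides of a block chain
# (rightmost blocks on "+", leftmost on "-").
truncate_blocks <- function(b, len, strand) {
  w <- b[, 2L] - b[, 1L]
  if (len >= sum(w)) return(b)
  if (strand == "+") {
    csum <- rev(cumsum(rev(w)))         # bases in blocks i..n
    first <- max(which(csum >= len))
    b <- b[first:nrow(b), , drop = FALSE]
    b[1L, 1L] <- b[1L, 1L] + (csum[first] - len)
  } else {
    csum <- cumsum(w)                   # bases in blocks 1..i
    last <- min(which(csum >= len))
    b <- b[seq_len(last), , drop = FALSE]
    b[nrow(b), 2L] <- b[nrow(b), 2L] - (csum[last] - len)
  }
  b
}

#' Emit aligned reads from ground-truth molecules
#'
#' Converts each molecule's element chain to genomic exon blocks and
#' applies, in order: per-intron retention (Bernoulli, merging blocks
#' across retained introns), 3'-anchored truncation (poly(dT)-primed
#' libraries keep the 3' end), contaminant substitution (a read becomes
#' unbarcoded -- its tag region is random sequence -- or purely
#' intronic -- a single block wholly inside an annotated intron), and
#' per-base corruption of the 28-nt barcode-UMI tag. The ground-truth
#' linkage is retained in a sidecar table.
#'
#' @param truth A [generate_molecules()] result.
#' @param models The matching [generate_gene_models()] result.
#' @param config The same [sim_config()].
#' @return Object of class `sim_reads`: data frames `reads` (read
#'   table: read_id, chrom, strand, start, end, blocks, gene_id),
#'   `tags` (read_id, tag_region), `link` (read_id, mol_id, class),
#'   `celltype_map` (barcode, celltype), `illumina_tags` (gene_id,
#'   barcode, umi; the short-read tag reference), and the `whitelist`.
#' @export
emit_reads <- function(truth, models, config = models$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(models, "gene_models"))
  mol <- truth$molecules
  if (nrow(mol) == 0L) stop("ground truth holds no molecules")
  with_seed(config$seed + 2L, {
    ex <- models$exons
    n <- nrow(mol)
    p_unb <- unname(config$contaminant_fracs["unbarcoded"])
    p_int <- unname(config$contaminant_fracs["intronic"])
    u <- stats::runif(n)
    cls <- ifelse(u < p_unb, "unbarcoded",
                  ifelse(u < p_unb + p_int, "intronic", "molecule"))
    # per-gene intron catalog (gaps between union exon intervals)
    introns <- lapply(split(ex, ex$gene_id), function(e) {
      ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
      gaps <- IRanges::gaps(ir)
      cbind(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
    })
    strand_of <- stats::setNames(models$genes$strand, models$genes$gene_id)
    blocks <- character(n); rstart <- integer(n); rend <- integer(n)
    slot_list <- strsplit(mol$incl_slots, ",", fixed = TRUE)
    for (i in seq_len(n)) {
      gid <- mol$gene_id[i]
      if (cls[i] == "intronic") {
        gi <- introns[[gid]]
        gi <- gi[gi[, 2L] - gi[, 1L] >= 40L, , drop = FALSE]
        row <- gi[sample.int(nrow(gi), 1L), ]
        len <- min(200L, row[2L] - row[1L])
        s <- row[1L] + sample.int(row[2L] - row[1L] - len + 1L, 1L) - 1L
        b <- cbind(start = s, end = s + len)
      } else {
        slots <- as.integer(slot_list[[i]])
        rows <- ex[ex$gene_id == gid &
                     ((ex$role == "first" & ex$variant == mol$tss_var[i]) |
                        (ex$role == "internal" & ex$slot %in% slots) |
                        (ex$role == "last" & ex$variant == mol$polya_var[i])), ]
        b <- chain_to_blocks(rows, config$intron_retention_prob)
        if (config$truncation$prob > 0 &&
            stats::runif(1L) < config$truncation$prob) {
          repeat {
            len <- stats::rnorm(1L, config$truncation$mean, config$truncation$sd)
            if (len > 0) break
          }
          len <- max(50L, min(round(len), sum(b[, 2L] - b[, 1L])))
          b <- truncate_blocks(b, len, strand_of[[gid]])
        }
      }
      blocks[i] <- format_blocks(b)
      rstart[i] <- b[1L, 1L]; rend[i] <- b[nrow(b), 2L]
    }
    true_tag <- paste0(mol$barcode, mol$umi)
    zero_noise <- config$tag_error_rates$sub == 0 &&
      config$tag_error_rates$ins == 0 && config$tag_error_rates$del == 0
    obs_tag <- if (zero_noise) true_tag
    else vapply(true_tag, corrupt_tag, character(1),
                rates = config$tag_error_rates, USE.NAMES = FALSE)
    obs_tag[cls == "unbarcoded"] <- random_dna(sum(cls == "unbarcoded"), 28L)
    tag_region <- paste0(random_dna(n, 12L), obs_tag, random_dna(n, 20L))
    read_id <- sprintf("r%06d", seq_len(n))
    reads <- data.frame(read_id = read_id, chrom = "chrS",
                        strand = strand_of[mol$gene_id],
                        start = rstart, end = rend, blocks = blocks,
                        gene_id = mol$gene_id, stringsAsFactors = FALSE,
                        row.names = NULL)
    structure(list(
      reads = reads,
      tags = data.frame(read_id = read_id, tag_region = tag_region,
                        stringsAsFactors = FALSE),
      link = data.frame(read_id = read_id, mol_id = mol$mol_id,
                        class = cls, stringsAsFactors = FALSE),
      celltype_map = truth$nuclei[, c("barcode", "celltype")],
      illumina_tags = mol[, c("gene_id", "barcode", "umi")],
      whitelist = truth$whitelist), class = "sim_reads")
  })
}

#' Run the whole generator
#'
#' Convenience wrapper: [generate_gene_models()],
#' [generate_molecules()], [emit_reads()].
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_fixture`: list with `models`, `truth`,
#'   `emitted`.
#' @export
simulate_fixture <- function(config = sim_config()) {
  models <- generate_gene_models(config)
  truth <- generate_molecules(models, config)
  emitted <- emit_reads(truth, models, config)
  structure(list(models = models, truth = truth, emitted = emitted),
            class = "sim_fixture")
}
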