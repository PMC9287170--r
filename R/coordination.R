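# Exon-pair coordination: 2x2 association tables, chi-squared testing
# with the testability criterion, log-odds effect sizes, cell-type
# tracing.

#' Enumerate alternative exon pairs within genes
#'
#' All within-gene pairs of retained alternative exons, ordered by
#' coordinate. A pair is `adjacent` when no annotated exon of the gene
#' lies strictly between the two intervals, `distant` otherwise.
#'
#' @param alt_exons Alternative-exon data frame (needs `exon_id`,
#'   `gene_id`, `start`, `end`).
#' @param models Gene models (annotated exons define adjacency).
#' @return Data frame with `pair_id`, `gene_id`, `exon1`, `exon2`
#'   (coordinate-ordered ids) and `adjacency`.
#' @export
enumerate_pairs <- function(alt_exons, models) {
  out <- list()
  ann <- models$exons
  for (gid in unique(alt_exons$gene_id)) {
    e <- alt_exons[alt_exons$gene_id == gid, , drop = FALSE]
    e <- e[order(e$start, e$end), , drop = FALSE]
    if (nrow(e) < 2L) next
    ae <- ann[ann$gene_id == gid, , drop = FALSE]
    for (i in seq_len(nrow(e) - 1L)) for (j in (i + 1L):nrow(e)) {
      between <- ae$start >= e$end[i] & ae$end <= e$start[j]
      out[[length(out) + 1L]] <- data.frame(
        pair_id = paste(e$exon_id[i], e$exon_id[j], sep = "|"),
        gene_id = gid, exon1 = e$exon_id[i], exon2 = e$exon_id[j],
        adjacency = if (any(between)) "distant" else "adjacent",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pair_id = character(0), gene_id = character(0),
                      exon1 = character(0), exon2 = character(0),
                      adjacency = character(0)))
  do.call(rbind, out)
}

#' 2x2 inclusion table for an exon pair
#'
#' A molecule contributes only if it yields a determinate full call
#' for *both* exons: inclusion with both splice sites matched, or a
#' skip with >= `flank` aligned bases on each side. Exon-terminal
#' partial support (`acc_in` / `don_in`) is excluded from pairing.
#'
#' @param exon1,exon2 Exon rows (coordinate order).
#' @param molecules Deduplicated read table of the gene (one context).
#' @param bt Optional precomputed block table.
#' @param flank Skip-call flank (bp).
#' @return Named counts `c(in_in, in_out, out_in, out_out)`.
#' @export
build_pair_counts <- function(exon1, exon2, molecules = NULL, bt = NULL,
                              flank = 50L) {
  if (is.null(bt)) bt <- build_block_table(molecules)
  c1 <- exon_calls(exon1, bt, flank)
  c2 <- exon_calls(exon2, bt, flank)
  det1 <- c1 %in% c("in", "out")
  det2 <- c2 %in% c("in", "out")
  use <- det1 & det2
  c(in_in = sum(use & c1 == "in" & c2 == "in"),
    in_out = sum(use & c1 == "in" & c2 == "out"),
    out_in = sum(use & c1 == "out" & c2 == "in"),
    out_out = sum(use & c1 == "out" & c2 == "out"))
}

#' Test one exon pair for coordination
#'
#' Applies the chi-squared testability criterion to the 2x2 table; if
#' testable, computes the Pearson chi-squared p-value (no continuity
#' correction by default), the odds ratio and log-odds (zeros set to
#' 0.5), the co-inclusion score `in_in / total` and the inclusion
#' ratio `in_in / (in_in + out_out)`. Significance is decided by the
#' caller after FDR adjustment: `FDR <= alpha` and `|log_odds| >=
#' lor_threshold`.
#'
#' @param counts Named counts from [build_pair_counts()].
#' @param base Log-odds base (default 2).
#' @param correct Yates continuity correction (default off).
#' @return One-row data frame with `in_in..out_out`, `chi2`,
#'   `p_value`, `odds_ratio`, `log_odds`, `co_inclusion`,
#'   `inclusion_ratio`, `direction`, `testability`.
#' @export
test_pair <- function(counts, base = 2, correct = FALSE) {
  M <- matrix(counts[c("in_in", "in_out", "out_in", "out_out")], nrow = 2L,
              byrow = TRUE)
  crit <- chi2_criterion(M)
  or <- odds_ratio(counts, base = base)
  tot <- sum(counts)
  res <- data.frame(in_in = counts[["in_in"]], in_out = counts[["in_out"]],
                    out_in = counts[["out_in"]], out_out = counts[["out_out"]],
                    chi2 = NA_real_, p_value = NA_real_,
                    odds_ratio = or$odds_ratio, log_odds = or$log_odds,
                    co_inclusion = if (tot > 0) counts[["in_in"]] / tot else NA_real_,
                    inclusion_ratio = if (counts[["in_in"]] + counts[["out_out"]] > 0)
                      counts[["in_in"]] / (counts[["in_in"]] + counts[["out_out"]])
                    else NA_real_,
                    direction = if (or$log_odds > 0) "mutual_inclusion"
                    else "mutual_exclusion",
                    testability = crit$class, stringsAsFactors = FALSE)
  if (crit$class == "testable") {
    ch <- pearson_chi2(M, correct = correct)
    res$chi2 <- ch$statistic
    res$p_value <- ch$p_value
  }
  res
}

#' Build and test all pairs in one context
#'
#' Counts, tests and BY-adjusts every enumerated pair over the given
#' molecules; the significance flag combines `FDR <= alpha` with
#' `|log_odds| >= lor_threshold`.
#'
#' @param pairs Output of [enumerate_pairs()].
#' @param exons Exon data frame the pair ids refer to.
#' @param molecules Deduplicated read table (one context).
#' @param alpha FDR threshold (default 0.05).
#' @param lor_threshold Absolute log-odds threshold (default 1).
#' @param base,correct,flank Passed through.
#' @return `pairs` with count/test columns, `fdr` and `significant`.
#' @export
test_pairs <- function(pairs, exons, molecules, alpha = 0.05,
                       lor_threshold = 1, base = 2, correct = FALSE,
                       flank = 50L) {
  rows <- list()
  for (gid in unique(pairs$gene_id)) {
    gp <- pairs[pairs$gene_id == gid, , drop = FALSE]
    gm <- molecules[molecules$gene_id == gid, , drop = FALSE]
    bt <- if (nrow(gm)) build_block_table(gm)
    for (i in seq_len(nrow(gp))) {
      e1 <- exons[exons$exon_id == gp$exon1[i], ]
      e2 <- exons[exons$exon_id == gp$exon2[i], ]
      cnt <- if (is.null(bt)) c(in_in = 0L, in_out = 0L, out_in = 0L,
                                out_out = 0L)
      else build_pair_counts(e1, e2, bt = bt, flank = flank)
      rows[[length(rows) + 1L]] <- cbind(gp[i, , drop = FALSE],
                                         test_pair(cnt, base = base,
                                                   correct = correct))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- adjust_fdr_by(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr <= alpha &
    abs(res$log_odds) >= lor_threshold
  res
}

#' Keep one exon pair per gene
#'
#' `mode = "significance"` (default): the lowest-FDR pair, ties broken
#' by leftmost coordinates (pair id order). `mode = "conservation"`:
#' the pair with the smallest absolute log-odds, as used for the
#' conservation analysis.
#'
#' @param results Output of [test_pairs()].
#' @param mode Selection rule.
#' @return Filtered results, one row per gene.
#' @export
select_one_per_gene <- function(results,
                                mode = c("significance", "conservation")) {
  mode <- match.arg(mode)
  keyfun <- if (mode == "significance")
    function(r) order(is.na(r$fdr), r$fdr, r$pair_id)
  else function(r) order(abs(r$log_odds), r$pair_id)
  out <- do.call(rbind, lapply(split(results, results$gene_id), function(r)
    r[keyfun(r)[1L], , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Trace a set of coordinated pairs into cell types
#'
#' For each pseudo-bulk-significant pair and each cell type, rebuilds
#' the 2x2 table from that cell type's molecules, applies the
#' testability criterion, and classifies:
#' `significant_same` / `significant_opposite` (cell-type FDR <= alpha
#' and `|log_odds| >= lor_threshold`, direction compared to the
#' pseudo-bulk log-odds sign), `not_significant`, `constitutive`, or
#' `low_counts`. The BY adjustment is recomputed within the traced set
#' (all testable cell-type tables of this call).
#'
#' @param sig_pairs Pseudo-bulk-significant rows of [test_pairs()]
#'   (needs `log_odds` for the direction).
#' @param exons Exon data frame.
#' @param molecules Deduplicated read table with `celltype`.
#' @param celltypes Cell types to trace (default: all present).
#' @param alpha,lor_threshold,base,flank As in [test_pairs()].
#' @return Long data frame: `pair_id`, `celltype`, counts, `log_odds`,
#'   `p_value`, `fdr`, `class`.
#' @export
trace_pair_to_celltypes <- function(sig_pairs, exons, molecules,
                                    celltypes = NULL, alpha = 0.05,
                                    lor_threshold = 1, base = 2,
                                    flank = 50L) {
  if (is.null(celltypes))
    celltypes <- sort(unique(molecules$celltype[!is.na(molecules$celltype)]))
  rows <- list()
  for (i in seq_len(nrow(sig_pairs))) {
    e1 <- exons[exons$exon_id == sig_pairs$exon1[i], ]
    e2 <- exons[exons$exon_id == sig_pairs$exon2[i], ]
    for (ct in celltypes) {
      gm <- molecules[!is.na(molecules$celltype) & molecules$celltype == ct &
                        molecules$gene_id == sig_pairs$gene_id[i], ,
                      drop = FALSE]
      cnt <- if (nrow(gm))
        build_pair_counts(e1, e2, molecules = gm, flank = flank)
      else c(in_in = 0L, in_out = 0L, out_in = 0L, out_out = 0L)
      tp <- test_pair(cnt, base = base)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sig_pairs$pair_id[i], celltype = ct, tp,
        bulk_log_odds = sig_pairs$log_odds[i], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- adjust_fdr_by(res$p_value)
  sig <- !is.na(res$fdr) & res$fdr <= alpha & abs(res$log_odds) >= lor_threshold
  same <- sign(res$log_odds) == sign(res$bulk_log_odds)
  res$class <- ifelse(res$testability == "low_counts", "low_counts",
               ifelse(res$testability == "constitutive", "constitutive",
               ifelse(sig & same, "significant_same",
               ifelse(sig, "significant_opposite", "not_significant"))))
  res
}

#' Disease enrichment of coordinated-pair membership
#'
#' Two-sided Fisher's exact test on the 2x2 of (exon belongs to a
#' coordinated pair of the given class) x (exon is
#' disease-associated).
#'
#' @param in_pair,is_disease Logical vectors over exons.
#' @return List with `odds_ratio`, `p_value`, `table`.
#' @export
disease_pair_enrichment <- function(in_pair, is_disease) {
  tab <- table(factor(in_pair, c(TRUE, FALSE)),
               factor(is_disease, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = NA_real_, table = tab))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Conservation versus coordination strength
#'
#' Pearson product-moment correlation (two-sided) between the minimum
#' conservation score of each pair and its absolute log-odds. The
#' grouped variant splits pairs at score 0.5 into `[0, 0.5]` and
#' `(0.5, 1]` bins and compares `|log_odds|` and `inclusion_ratio`
#' between bins by rank-sum test.
#'
#' @param results Pair results (needs `log_odds`, `inclusion_ratio`,
#'   `exon1`, `exon2`).
#' @param scores Named numeric vector: conservation score in `[0, 1]`
#'   per exon id.
#' @param grouped Also compute the two-bin comparison.
#' @return List with `r`, `p_value`, `n`, and (grouped) `group_p_lor`,
#'   `group_p_inclusion`.
#' @export
conservation_vs_coordination <- function(results, scores, grouped = FALSE) {
  s <- pmin(scores[results$exon1], scores[results$exon2])
  lor <- abs(results$log_odds)
  ok <- !is.na(s) & !is.na(lor)
  out <- list(r = NA_real_, p_value = NA_real_, n = sum(ok))
  if (sum(ok) >= 3L && stats::sd(s[ok]) > 0 && stats::sd(lor[ok]) > 0) {
    ct <- stats::cor.test(s[ok], lor[ok], method = "pearson",
                          alternative = "two.sided")
    out$r <- unname(ct$estimate)
    out$p_value <- ct$p.value
  }
  if (grouped) {
    lowg <- ok & s <= 0.5
    highg <- ok & s > 0.5
    wtest <- function(v) {
      if (sum(lowg) == 0L || sum(highg) == 0L) return(NA_real_)
      suppressWarnings(stats::wilcox.test(v[lowg], v[highg])$p.value)
    }
    out$group_p_lor <- wtest(lor)
    out$group_p_inclusion <- wtest(results$inclusion_ratio)
  }
  out
}
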