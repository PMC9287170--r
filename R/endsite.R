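# End-site x exon coordination: n x 2 matrices, delta-pi, testability.

# Flanking annotated-exon boundaries of an exon within its gene:
# end coordinate of the closest annotated exon strictly left, start of
# the closest strictly right (genomic). NA when none exists.
flanking_boundaries <- function(exon, ann_gene) {
  left <- ann_gene$end[ann_gene$end <= exon$start]
  right <- ann_gene$start[ann_gene$start >= exon$end]
  list(prev_end = if (length(left)) max(left) else NA_integer_,
       next_start = if (length(right)) min(right) else NA_integer_)
}

#' Build the end-site x exon count matrix
#'
#' Rows are the distinct end sites assigned to the gene's molecules,
#' columns the include / exclude counts for one internal exon. A
#' molecule contributes only if (a) it carries an end-site assignment,
#' (b) it yields a determinate include/exclude call for the exon, and
#' (c) it satisfies the positional constraint: for TSS matrices the
#' site must lie upstream of the intron preceding the exon and the
#' read must extend beyond the end of the following intron; for polyA
#' matrices the mirror (site downstream of the following intron, read
#' extending beyond the start of the preceding intron). Genes with
#' fewer than `min_gene_reads` molecules in the context are withheld.
#'
#' @param exon One exon row (`gene_id`, `start`, `end`, `strand`).
#' @param kind `"TSS"` or `"polyA"`.
#' @param molecules Deduplicated read table of the gene with `tss_id`
#'   / `polya_id` columns (one context).
#' @param models Gene models (flanking annotated exons define the
#'   introns); end-site positions looked up from `sites`.
#' @param sites Peak data frame (`site_id`, `pos`).
#' @param min_gene_reads Gene depth threshold (default 25).
#' @param flank Skip-call flank (bp).
#' @param row_sites Optional site ids fixing the matrix rows (zero
#'   rows kept). Cell-type tracing passes the pseudo-bulk rows here so
#'   that a site unused in one cell type surfaces as a constitutive
#'   row rather than vanishing.
#' @return An `endsite_matrix` list (`M`, `kind`, `exon_id`,
#'   `gene_id`, `n_dropped_positional`), or `NULL` when the gene is
#'   below depth (withheld, with a message attribute).
#' @export
build_endsite_matrix <- function(exon, kind = c("TSS", "polyA"), molecules,
                                 models, sites, min_gene_reads = 25L,
                                 flank = 50L, row_sites = NULL) {
  kind <- match.arg(kind)
  if (nrow(molecules) < min_gene_reads) return(NULL)
  site_col <- if (kind == "TSS") "tss_id" else "polya_id"
  bt <- build_block_table(molecules)
  calls <- exon_calls(exon, bt, flank)
  det <- calls %in% c("in", "out")
  site <- molecules[[site_col]]
  ann <- models$exons[models$exons$gene_id == exon$gene_id, , drop = FALSE]
  fb <- flanking_boundaries(exon, ann)
  pos <- sites$pos[match(site, sites$site_id)]
  plus <- exon$strand == "+"
  # genomic left/right of the exon map to preceding/following introns
  # by strand: on "+" the preceding intron is the left gap.
  if (kind == "TSS") {
    ok_site <- if (plus) pos <= fb$prev_end else pos >= fb$next_start
    ok_span <- if (plus) molecules$end > fb$next_start
    else molecules$start < fb$prev_end
  } else {
    ok_site <- if (plus) pos >= fb$next_start else pos <= fb$prev_end
    ok_span <- if (plus) molecules$start < fb$prev_end
    else molecules$end > fb$next_start
  }
  use <- det & !is.na(site) & !is.na(ok_site) & ok_site & ok_span
  use[is.na(use)] <- FALSE
  n_dropped <- sum(det & !is.na(site)) - sum(use)
  lev <- row_sites %||% sort(unique(site[use]))
  if (!length(lev)) {
    M <- matrix(integer(0), nrow = 0L, ncol = 2L,
                dimnames = list(NULL, c("include", "exclude")))
  } else {
    inc <- factor(calls[use], levels = c("in", "out"))
    M <- as.matrix(table(factor(site[use], levels = lev), inc))
    colnames(M) <- c("include", "exclude")
  }
  structure(list(M = M, kind = kind, exon_id = exon$exon_id %||% NA_character_,
                 gene_id = exon$gene_id,
                 n_dropped_positional = n_dropped),
            class = "endsite_matrix")
}

#' Maximum change in exon inclusion across end sites
#'
#' The largest minus the smallest per-row inclusion fraction of an end
#' site x (include, exclude) matrix; rows with zero counts are
#' ignored. Needs at least two usable rows, else `NA`. Invariant to
#' scaling the matrix by a positive constant.
#'
#' @param M Count matrix, columns (include, exclude).
#' @return Delta-pi in `[0, 1]`, or `NA`.
#' @export
delta_pi <- function(M) {
  M <- as.matrix(M)
  rs <- rowSums(M)
  use <- rs > 0
  if (sum(use) < 2L) return(NA_real_)
  frac <- M[use, 1L] / rs[use]
  max(frac) - min(frac)
}

#' Test one end-site matrix for coordination
#'
#' Applies the chi-squared testability criterion; when testable,
#' computes the Pearson chi-squared p-value on the n x 2 matrix
#' (df = n - 1, zero-sum rows dropped) with delta-pi as effect size.
#' FDR over a collection of matrices is handled by [test_endsites()].
#'
#' @param em An `endsite_matrix` or a bare count matrix.
#' @return One-row data frame: `n_rows`, `chi2`, `p_value`,
#'   `delta_pi`, `testability`, `constitutive_dim`.
#' @export
test_endsite <- function(em) {
  M <- if (inherits(em, "endsite_matrix")) em$M else as.matrix(em)
  crit <- chi2_criterion(M)
  const_dim <- if (crit$class == "constitutive") {
    paste(c(sprintf("row%d", crit$constitutive_rows),
            sprintf("col%d", crit$constitutive_cols)), collapse = ",")
  } else NA_character_
  res <- data.frame(n_rows = nrow(M), chi2 = NA_real_, p_value = NA_real_,
                    delta_pi = delta_pi(M), testability = crit$class,
                    constitutive_dim = const_dim, stringsAsFactors = FALSE)
  if (crit$class == "testable") {
    ch <- pearson_chi2(M)
    res$chi2 <- ch$statistic
    res$p_value <- ch$p_value
  }
  res
}

#' Test a collection of end-site matrices with BY-FDR
#'
#' @param ems List of `endsite_matrix` objects (one kind).
#' @param alpha FDR threshold for the significance flag.
#' @return Data frame, one row per matrix, with `fdr` and
#'   `significant`.
#' @export
test_endsites <- function(ems, alpha = 0.05) {
  rows <- lapply(ems, function(em) {
    data.frame(gene_id = em$gene_id, exon_id = em$exon_id, kind = em$kind,
               row_sites = paste(rownames(em$M), collapse = ","),
               test_endsite(em), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- adjust_fdr_by(res$p_value)
  res$significant <- !is.na(res$fdr) & res$fdr <= alpha
  res
}

#' Trace end-site coordination into cell types
#'
#' For each pseudo-bulk-significant end-site matrix, rebuilds the
#' matrix per cell type and classifies it as `significant`,
#' `not_significant`, `low_counts` or `constitutive` (an exon or end
#' site becoming constitutively used in that cell type). FDR is
#' recomputed within the traced set.
#'
#' @param sig Rows of [test_endsites()] to trace (needs `exon_id`,
#'   `gene_id`, `kind`).
#' @param exons Exon data frame the ids refer to.
#' @param molecules Deduplicated read table with `celltype`.
#' @param models,sites,min_gene_reads,flank As in
#'   [build_endsite_matrix()].
#' @param celltypes Cell types to trace (default all present).
#' @param alpha FDR threshold.
#' @return Long data frame: `exon_id`, `kind`, `celltype`, test
#'   columns, `class`.
#' @export
trace_endsite_to_celltypes <- function(sig, exons, molecules, models, sites,
                                       celltypes = NULL, alpha = 0.05,
                                       min_gene_reads = 25L, flank = 50L) {
  if (is.null(celltypes))
    celltypes <- sort(unique(molecules$celltype[!is.na(molecules$celltype)]))
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    exon <- exons[exons$exon_id == sig$exon_id[i], ]
    rs <- if ("row_sites" %in% names(sig) && nzchar(sig$row_sites[i]))
      strsplit(sig$row_sites[i], ",", fixed = TRUE)[[1L]]
    for (ct in celltypes) {
      gm <- molecules[!is.na(molecules$celltype) & molecules$celltype == ct &
                        molecules$gene_id == sig$gene_id[i], , drop = FALSE]
      em <- build_endsite_matrix(exon, sig$kind[i], gm, models, sites,
                                 min_gene_reads = min_gene_reads,
                                 flank = flank, row_sites = rs)
      tr <- if (is.null(em))
        data.frame(n_rows = 0L, chi2 = NA_real_, p_value = NA_real_,
                   delta_pi = NA_real_, testability = "low_counts",
                   constitutive_dim = NA_character_, stringsAsFactors = FALSE)
      else test_endsite(em)
      rows[[length(rows) + 1L]] <- data.frame(exon_id = sig$exon_id[i],
                                              kind = sig$kind[i],
                                              celltype = ct, tr,
                                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- adjust_fdr_by(res$p_value)
  issig <- !is.na(res$fdr) & res$fdr <= alpha
  res$class <- ifelse(res$testability == "constitutive", "constitutive",
               ifelse(res$testability == "low_counts", "low_counts",
               ifelse(issig, "significant", "not_significant")))
  res
}
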