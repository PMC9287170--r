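# End-to-end driver: tags -> dedup -> assignment -> PSI ->
# coordination -> end sites -> reports.

#' Pipeline thresholds
#'
#' All defaults are the analysis' canonical values: 50-bp end-site
#' window, PSI window `[0.05, 0.95]`, coverage ratio 0.8, 50-nt skip
#' flank, 70-nt novel-exon non-exonic rule, per-cell-type depth 10,
#' gene depth 25 for end-site matrices, FDR 0.05, absolute log-odds
#' threshold 1, microexon cutoff 27 nt, variability cuts 0.25 / 0.75,
#' novel-exon quadrant cuts 0.5, log base 2.
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` list (every value echoed into the run log).
#' @export
run_config <- function(...) {
  cfg <- list(endsite_window = 50L, psi_window = c(0.05, 0.95),
              min_coverage = 0.8, skip_flank = 50L, novel_nonexonic = 70L,
              celltype_depth = 10L, gene_depth_endsite = 25L,
              alpha = 0.05, lor_threshold = 1, microexon_max = 27L,
              variability_cuts = c(0.25, 0.75), quadrant_cut = 0.5,
              log_base = 2, max_scan = 200L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown run_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Replicate correlation of gene expression
#'
#' Pearson correlation of `log10(TPM + 1)` per gene between two
#' molecule tables (union of genes; absent genes count 0).
#'
#' @param mol1,mol2 Molecule tables with `gene_id`.
#' @return Pearson r.
#' @export
replicate_correlation <- function(mol1, mol2) {
  genes <- union(mol1$gene_id, mol2$gene_id)
  c1 <- table(factor(mol1$gene_id, genes))
  c2 <- table(factor(mol2$gene_id, genes))
  stats::cor(log_tpm(as.numeric(c1)), log_tpm(as.numeric(c2)))
}

#' Run the full analysis pipeline
#'
#' Sequences all stages over a fixture directory (see
#' [write_fixture()]) or an equivalent list of in-memory inputs:
#' tag matching and UMI correction against the short-read reference,
#' molecule deduplication, cell-type attachment, end-site assignment
#' and completeness, on-target and saturation metrics, exon discovery,
#' PSI quantification and filtering, cell-type variability, exon-pair
#' coordination with cell-type tracing, and end-site coordination with
#' cell-type tracing. Deterministic given `config$seed`.
#'
#' @param inputs Fixture directory path, or a list with `models`,
#'   `tss`, `polya`, `reads`, `tags`, `illumina_tags`, `celltype_map`,
#'   `whitelist`.
#' @param config A [run_config()].
#' @param replicate_inputs Optional second input set; adds a
#'   replicate-correlation entry to the metrics.
#' @return A `result_bundle` list: `molecules`, `exons`, `psi`,
#'   `psi_celltype`, `variability`, `pairs`, `pair_trace`, `endsite`,
#'   `endsite_trace`, `metrics`, `log`.
#' @export
run_pipeline <- function(inputs, config = run_config(),
                         replicate_inputs = NULL) {
  if (is.character(inputs)) inputs <- read_fixture(inputs)
  log <- list(r_version = as.character(getRversion()),
              seed = config$seed, parameters = unclass(config))
  ref <- build_tag_reference(inputs$illumina_tags)
  mols <- process_tags(inputs$reads, inputs$tags, ref,
                       max_scan = config$max_scan)
  n_raw <- nrow(inputs$reads)
  ct_map <- stats::setNames(inputs$celltype_map$celltype,
                            inputs$celltype_map$barcode)
  mols$celltype <- unname(ct_map[mols$barcode])
  mols <- assign_end_sites(mols, inputs$tss, inputs$polya,
                           window = config$endsite_window)
  mols <- classify_completeness(mols, inputs$tss, inputs$polya,
                                window = config$endsite_window)
  mols$splice_status <- splice_status(mols, inputs$models)
  metrics <- list(
    n_raw_reads = n_raw,
    n_molecules = nrow(mols),
    barcode_rate = 1 - attr(mols, "n_unmatched") / n_raw,
    on_target_rate = on_target_rate(inputs$reads, inputs$models$exons),
    five_prime_complete = mean(mols$five_prime_complete),
    three_prime_complete = mean(mols$three_prime_complete),
    splice_status = as.list(table(mols$splice_status)),
    mean_exon_ratio = mean(exon_ratio(mols, inputs$models), na.rm = TRUE))
  depths <- unique(pmax(1L, round(nrow(mols) * c(0.25, 0.5, 1))))
  metrics$saturation <- saturation_curve(mols, depths, config$seed)
  if (!is.null(replicate_inputs)) {
    if (is.character(replicate_inputs))
      replicate_inputs <- read_fixture(replicate_inputs)
    ref2 <- build_tag_reference(replicate_inputs$illumina_tags)
    mols2 <- process_tags(replicate_inputs$reads, replicate_inputs$tags,
                          ref2, max_scan = config$max_scan)
    metrics$replicate_r <- replicate_correlation(mols, mols2)
  }
  exons <- discover_internal_exons(mols, inputs$models)
  psi <- psi_table(exons, mols, flank = config$skip_flank)
  bulk <- merge(psi[psi$context == "pseudo_bulk", ], exons, by = "exon_id")
  alt <- filter_alternative_exons(bulk, psi_window = config$psi_window,
                                  min_coverage = config$min_coverage,
                                  novel_nonexonic = config$novel_nonexonic)
  ctp <- celltype_psi(psi, min_tot = config$celltype_depth)
  variability <- psi_variability(ctp, cuts = config$variability_cuts)
  pairs <- enumerate_pairs(alt, inputs$models)
  pair_res <- if (nrow(pairs))
    test_pairs(pairs, exons, mols, alpha = config$alpha,
               lor_threshold = config$lor_threshold, base = config$log_base,
               flank = config$skip_flank)
  else NULL
  pair_trace <- if (!is.null(pair_res) && any(pair_res$significant))
    trace_pair_to_celltypes(pair_res[pair_res$significant, ], exons, mols,
                            alpha = config$alpha,
                            lor_threshold = config$lor_threshold,
                            base = config$log_base,
                            flank = config$skip_flank)
  else NULL
  # end-site matrices for all alternative exons, both kinds
  ems <- list()
  for (i in seq_len(nrow(alt))) {
    exon <- alt[i, ]
    gm <- mols[mols$gene_id == exon$gene_id, , drop = FALSE]
    for (kind in c("TSS", "polyA")) {
      sites <- if (kind == "TSS") inputs$tss else inputs$polya
      em <- build_endsite_matrix(exon, kind, gm, inputs$models, sites,
                                 min_gene_reads = config$gene_depth_endsite,
                                 flank = config$skip_flank)
      # a single end site has nothing to coordinate with
      if (!is.null(em) && nrow(em$M) >= 2L) ems[[length(ems) + 1L]] <- em
    }
  }
  endsite <- if (length(ems)) test_endsites(ems, alpha = config$alpha)
  endsite_trace <- if (!is.null(endsite) && any(endsite$significant))
    trace_endsite_to_celltypes(endsite[endsite$significant, ], alt, mols,
                               inputs$models,
                               rbind(inputs$tss, inputs$polya),
                               alpha = config$alpha,
                               min_gene_reads = config$gene_depth_endsite,
                               flank = config$skip_flank)
  else NULL
  structure(list(molecules = mols, exons = exons, psi = psi,
                 alternative_exons = alt, psi_celltype = ctp,
                 variability = variability, pairs = pair_res,
                 pair_trace = pair_trace, endsite = endsite,
                 endsite_trace = endsite_trace, metrics = metrics,
                 log = log), class = "result_bundle")
}

#' Write a result bundle to disk
#'
#' TSV tables plus a JSON metrics/log file.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_tsv(bundle$molecules, fp("molecules.tsv"))
  write_tsv(bundle$psi, fp("psi.tsv"))
  write_tsv(bundle$variability, fp("variability.tsv"))
  if (!is.null(bundle$pairs)) write_tsv(bundle$pairs, fp("coordination.tsv"))
  if (!is.null(bundle$pair_trace))
    write_tsv(bundle$pair_trace, fp("coordination_celltype.tsv"))
  if (!is.null(bundle$endsite)) write_tsv(bundle$endsite, fp("endsite.tsv"))
  if (!is.null(bundle$endsite_trace))
    write_tsv(bundle$endsite_trace, fp("endsite_celltype.tsv"))
  jsonlite::write_json(c(bundle$metrics, list(log = bundle$log)),
                       fp("metrics.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
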