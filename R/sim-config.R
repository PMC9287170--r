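#' Configuration for the synthetic read generator
#'
#' Bundles every tunable of the simulator: gene-model shape, cohort
#' structure, per-cell-type exon inclusion probabilities, planted
#' coordination effects, and the noise processes (intron retention,
#' 3'-anchored truncation, contaminant reads, tag-sequence errors).
#' Identical configurations (including `seed`) produce byte-identical
#' fixtures.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_genes Number of genes.
#' @param exons_per_gene Number of exon slots per gene (scalar, or
#'   `c(min, max)` range sampled per gene). Slot 1 is the constitutive
#'   first exon (with `n_tss` variants), the last slot the constitutive
#'   last exon (with `n_polya` variants); interior slots are
#'   alternative internal exons. Must be >= 3 so every alternative exon
#'   has constitutive flanks.
#' @param n_celltypes,celltype_names Cell types in the cohort.
#' @param nuclei_per_celltype Nuclei per cell type.
#' @param reads_per_nucleus Mean molecules per nucleus (Poisson).
#' @param n_tss,n_polya Number of alternative first / last exon
#'   variants per gene; each has one TSS / polyA site at its 5' / 3'
#'   end.
#' @param psi_spec `NULL` (drawn uniformly in `[0.15, 0.85]`) or a data
#'   frame with columns `gene_id`, `slot`, `celltype`, `psi` giving the
#'   per-cell-type inclusion probability of each internal exon slot.
#' @param planted_pairs List of [plant_pair()] objects.
#' @param intron_retention_prob Per-intron retention probability.
#' @param contaminant_fracs Named vector `c(unbarcoded =, intronic =)`:
#'   per-read probabilities of emitting an unbarcoded read or a purely
#'   intronic read instead of the clean molecule.
#' @param tag_error_rates List `list(sub =, ins =, del =, region =)`
#'   with per-base substitution / insertion / deletion probabilities
#'   applied to the 28-nt barcode-UMI tag; `region` is `"tag"` (whole
#'   28-mer) or `"umi"` (last 12 nt only).
#' @param truncation List `list(prob =, mean =, sd =)`: with
#'   probability `prob` a read keeps only its 3'-most `N(mean, sd)`
#'   transcribed nucleotides (poly(dT)-primed libraries lose 5' ends).
#' @param exon_len,intron_len `c(min, max)` uniform length ranges (nt).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 8L,
                       exons_per_gene = 7L,
                       n_celltypes = 4L,
                       celltype_names = NULL,
                       nuclei_per_celltype = 50L,
                       reads_per_nucleus = 40,
                       n_tss = 2L,
                       n_polya = 1L,
                       psi_spec = NULL,
                       planted_pairs = list(),
                       intron_retention_prob = 0.05,
                       contaminant_fracs = c(unbarcoded = 0.05, intronic = 0.05),
                       tag_error_rates = list(sub = 0.01, ins = 0.002,
                                              del = 0.002, region = "tag"),
                       truncation = list(prob = 0.15, mean = 800, sd = 300),
                       exon_len = c(90L, 210L),
                       intron_len = c(200L, 600L)) {
  if (length(exons_per_gene) == 1L) exons_per_gene <- rep(exons_per_gene, 2L)
  if (any(exons_per_gene < 3L))
    stop("exons_per_gene must be >= 3: an alternative internal exon needs constitutive flanks")
  if (is.null(celltype_names))
    celltype_names <- c("EN", "IN", "Astro", "Oligo", "OPC", "Micro")[seq_len(n_celltypes)]
  stopifnot(length(celltype_names) == n_celltypes,
            n_genes >= 1L, nuclei_per_celltype >= 1L, reads_per_nucleus > 0,
            n_tss >= 1L, n_polya >= 1L)
  probs <- c(intron_retention_prob, contaminant_fracs,
             tag_error_rates$sub, tag_error_rates$ins, tag_error_rates$del,
             truncation$prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (sum(contaminant_fracs) > 1) stop("contaminant fractions sum above 1")
  if (!tag_error_rates$region %in% c("tag", "umi"))
    stop("tag_error_rates$region must be 'tag' or 'umi'")
  if (!is.null(psi_spec)) {
    stopifnot(is.data.frame(psi_spec),
              all(c("gene_id", "slot", "celltype", "psi") %in% names(psi_spec)),
              all(psi_spec$psi >= 0 & psi_spec$psi <= 1))
  }
  for (pp in planted_pairs) {
    if (!inherits(pp, "planted_pair")) stop("planted_pairs must be plant_pair() objects")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 n_celltypes = as.integer(n_celltypes),
                 celltype_names = celltype_names,
                 nuclei_per_celltype = as.integer(nuclei_per_celltype),
                 reads_per_nucleus = reads_per_nucleus,
                 n_tss = as.integer(n_tss), n_polya = as.integer(n_polya),
                 psi_spec = psi_spec, planted_pairs = planted_pairs,
                 intron_retention_prob = intron_retention_prob,
                 contaminant_fracs = contaminant_fracs,
                 tag_error_rates = tag_error_rates,
                 truncation = truncation,
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len)),
            class = "sim_config")
}

#' Plant a coordination effect between two transcript elements
#'
#' Describes one planted pair for the generator: either two alternative
#' internal exons (adjacent or distant) whose inclusion indicators are
#' drawn from a bivariate Bernoulli at a per-cell-type odds ratio, or
#' an end site (TSS or polyA variant) paired with an exon. A
#' cell-type-constitutive configuration instead fixes an element's
#' usage in that cell type; per cell type, an odds ratio and a
#' constitutive flag are mutually exclusive.
#'
#' @param gene_id Gene identifier (e.g. `"G1"`).
#' @param kind One of `"exon_exon_adjacent"`, `"exon_exon_distant"`,
#'   `"tss_exon"`, `"exon_polya"`.
#' @param exons For exon-exon kinds, the two internal slot indices
#'   (adjacent means consecutive slots); for end-site kinds, the single
#'   internal slot index.
#' @param site For end-site kinds, the TSS / polyA variant index.
#' @param or_by_celltype Named numeric vector: target odds ratio per
#'   cell type (1 = independence). Cell types not named fall back to
#'   independent draws.
#' @param constitutive_by_celltype Named list: per cell type a list
#'   with any of `element` (1 or 2, which pair member; end-site pairs
#'   use 1 = the site, 2 = the exon) and `value` (1 = always used,
#'   0 = never).
#' @return An object of class `planted_pair`.
#' @export
plant_pair <- function(gene_id,
                       kind = c("exon_exon_adjacent", "exon_exon_distant",
                                "tss_exon", "exon_polya"),
                       exons = NULL, site = NULL,
                       or_by_celltype = numeric(0),
                       constitutive_by_celltype = list()) {
  kind <- match.arg(kind)
  if (startsWith(kind, "exon_exon")) {
    stopifnot(length(exons) == 2L, is.null(site))
    exons <- sort(as.integer(exons))
    if (kind == "exon_exon_adjacent" && diff(exons) != 1L)
      stop("adjacent pair must use consecutive slots")
    if (kind == "exon_exon_distant" && diff(exons) < 2L)
      stop("distant pair must have >= 1 intervening slot")
  } else {
    stopifnot(length(exons) == 1L, length(site) == 1L)
    exons <- as.integer(exons)
    site <- as.integer(site)
  }
  if (any(or_by_celltype <= 0)) stop("odds ratios must be > 0")
  both <- intersect(names(or_by_celltype), names(constitutive_by_celltype))
  if (length(both))
    stop("odds ratio and constitutive flag are mutually exclusive per cell type: ",
         paste(both, collapse = ", "))
  structure(list(gene_id = gene_id, kind = kind, exons = exons, site = site,
                 or_by_celltype = or_by_celltype,
                 constitutive_by_celltype = constitutive_by_celltype),
            class = "planted_pair")
}
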