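#' Generate synthetic gene models and end-site catalogs
#'
#' Builds GENCODE-style annotation for the simulated cohort: each gene
#' carries `n_tss` alternative first-exon variants (one TSS at each 5'
#' end), a chain of alternative internal exons, and `n_polya` last-exon
#' variants (one polyA site at each 3' end). Annotated transcripts are
#' all (first variant x last variant) full-inclusion isoforms plus one
#' skip-all isoform, so every gene has at least two isoforms and every
#' alternative exon is flanked by constitutive exons. Coordinates are
#' 0-based half-open internally; genes alternate strands.
#'
#' @param config A [sim_config()].
#' @return An object of class `gene_models`: a list with data frames
#'   `genes`, `exons`, `transcripts`, `transcript_exons`, `tss`,
#'   `polya`, `psi_spec`, and the `config`.
#' @export
generate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- exons <- tx <- txe <- tss <- polya <- list()
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("G%d", g)
      strand <- if (g %% 2L == 1L) "+" else "-"
      n_slots <- if (config$exons_per_gene[1L] == config$exons_per_gene[2L])
        config$exons_per_gene[1L]
      else sample(config$exons_per_gene[1L]:config$exons_per_gene[2L], 1L)
      n_internal <- n_slots - 2L
      rlen <- function(n, r) if (r[1L] == r[2L]) rep(r[1L], n) else
        sample(r[1L]:r[2L], n, replace = TRUE)
      # 5'->3' local layout: first variants, internal slots, last variants
      n_elem <- config$n_tss + n_internal + config$n_polya
      elens <- rlen(n_elem, config$exon_len)
      ilens <- rlen(n_elem - 1L, config$intron_len)
      starts <- cumsum(c(0L, elens[-n_elem] + ilens))
      ends <- starts + elens
      total <- ends[n_elem]
      offset <- (g - 1L) * 100000L
      if (strand == "+") {
        gs <- offset + starts; ge <- offset + ends
      } else {  # mirror so local 5'->3' runs right-to-left genomically
        gs <- offset + (total - ends); ge <- offset + (total - starts)
      }
      role <- c(rep("first", config$n_tss), rep("internal", n_internal),
                rep("last", config$n_polya))
      slot <- c(rep(1L, config$n_tss), seq_len(n_internal) + 1L,
                rep(n_internal + 2L, config$n_polya))
      variant <- c(seq_len(config$n_tss), rep(1L, n_internal),
                   seq_len(config$n_polya))
      eid <- sprintf("%s:S%d%s", gid, slot,
                     ifelse(role == "internal", "", letters[variant]))
      exons[[g]] <- data.frame(exon_id = eid, gene_id = gid, role = role,
                               slot = slot, variant = variant, chrom = "chrS",
                               start = gs, end = ge, strand = strand,
                               stringsAsFactors = FALSE)
      genes[[g]] <- data.frame(gene_id = gid, chrom = "chrS",
                               start = min(gs), end = max(ge),
                               strand = strand, n_slots = n_slots,
                               stringsAsFactors = FALSE)
      first_i <- which(role == "first"); last_i <- which(role == "last")
      tss[[g]] <- data.frame(site_id = sprintf("%s:TSS%d", gid, seq_len(config$n_tss)),
                             gene_id = gid, chrom = "chrS",
                             pos = if (strand == "+") gs[first_i] else ge[first_i],
                             strand = strand, variant = seq_len(config$n_tss),
                             stringsAsFactors = FALSE)
      polya[[g]] <- data.frame(site_id = sprintf("%s:PA%d", gid, seq_len(config$n_polya)),
                               gene_id = gid, chrom = "chrS",
                               pos = if (strand == "+") ge[last_i] else gs[last_i],
                               strand = strand, variant = seq_len(config$n_polya),
                               stringsAsFactors = FALSE)
      # transcripts: full-inclusion per (first, last) variant + one skip-all
      k <- 0L
      for (t in seq_len(config$n_tss)) for (q in seq_len(config$n_polya)) {
        k <- k + 1L
        tid <- sprintf("%s:T%d", gid, k)
        ids <- c(eid[first_i[t]], eid[role == "internal"], eid[last_i[q]])
        tx[[length(tx) + 1L]] <- data.frame(transcript_id = tid, gene_id = gid,
                                            stringsAsFactors = FALSE)
        txe[[length(txe) + 1L]] <- data.frame(transcript_id = tid, exon_id = ids,
                                              rank = seq_along(ids),
                                              stringsAsFactors = FALSE)
      }
      tid <- sprintf("%s:T%d", gid, k + 1L)
      ids <- c(eid[first_i[1L]], eid[last_i[1L]])
      tx[[length(tx) + 1L]] <- data.frame(transcript_id = tid, gene_id = gid,
                                          stringsAsFactors = FALSE)
      txe[[length(txe) + 1L]] <- data.frame(transcript_id = tid, exon_id = ids,
                                            rank = seq_along(ids),
                                            stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes); exons <- do.call(rbind, exons)
    psi <- config$psi_spec
    if (is.null(psi)) {
      internal <- exons[exons$role == "internal", ]
      psi <- expand.grid(exon_row = seq_len(nrow(internal)),
                         celltype = config$celltype_names,
                         stringsAsFactors = FALSE)
      psi <- data.frame(gene_id = internal$gene_id[psi$exon_row],
                        slot = internal$slot[psi$exon_row],
                        celltype = psi$celltype,
                        psi = round(stats::runif(nrow(psi), 0.15, 0.85), 4L),
                        stringsAsFactors = FALSE)
    }
    models <- structure(list(genes = genes, exons = exons,
                             transcripts = do.call(rbind, tx),
                             transcript_exons = do.call(rbind, txe),
                             tss = do.call(rbind, tss),
                             polya = do.call(rbind, polya),
                             psi_spec = psi, config = config),
                        class = "gene_models")
    validate_planted_pairs(models)
    models
  })
}

# Check that planted pairs reference existing elements and feasible triples.
validate_planted_pairs <- function(models) {
  cfg <- models$config
  for (pp in cfg$planted_pairs) {
    g <- models$genes[models$genes$gene_id == pp$gene_id, ]
    if (nrow(g) == 0L) stop("planted pair references unknown gene ", pp$gene_id)
    internal_slots <- 2L:(g$n_slots - 1L)
    if (!all(pp$exons %in% internal_slots))
      stop("planted pair ", pp$gene_id, ": slots must be internal (",
           min(internal_slots), "..", max(internal_slots), ")")
    if (pp$kind == "tss_exon" && pp$site > cfg$n_tss)
      stop("planted pair ", pp$gene_id, ": no such TSS variant")
    if (pp$kind == "exon_polya" && pp$site > cfg$n_polya)
      stop("planted pair ", pp$gene_id, ": no such polyA variant")
    for (ct in names(pp$or_by_celltype)) {
      if (!ct %in% cfg$celltype_names)
        stop("planted pair ", pp$gene_id, ": unknown cell type ", ct)
      p <- psi_lookup(models, pp$gene_id, pp$exons, ct)
      marg <- if (startsWith(pp$kind, "exon_exon")) p
      else c(1 / (if (pp$kind == "tss_exon") cfg$n_tss else cfg$n_polya), p)
      tryCatch(biv_bernoulli_probs(marg[1L], marg[2L], pp$or_by_celltype[[ct]]),
               error = function(e) stop("planted pair ", pp$gene_id, " (",
                                        ct, "): ", conditionMessage(e)))
    }
  }
  invisible(models)
}

psi_lookup <- function(models, gene_id, slots, celltype) {
  ps <- models$psi_spec
  vapply(slots, function(s) {
    v <- ps$psi[ps$gene_id == gene_id & ps$slot == s & ps$celltype == celltype]
    if (length(v) != 1L) stop("psi_spec missing for ", gene_id, " slot ", s,
                              " in ", celltype)
    v
  }, numeric(1))
}

#' Draw ground-truth molecules with planted effects
#'
#' Each nucleus (one 16-nt barcode per nucleus) yields a Poisson number
#' of molecules assigned uniformly to genes. Per molecule a TSS and a
#' polyA variant are chosen, and each internal exon's inclusion is a
#' Bernoulli draw at its cell-type inclusion probability -- except for
#' planted pairs, where the two indicators come from the bivariate
#' Bernoulli at the target odds ratio (end-site pairs draw the
#' site-usage indicator jointly with the exon), and cell-type
#' constitutive configurations fix the flagged element. `(barcode, UMI,
#' gene)` triplets are unique by construction.
#'
#' @param models A [generate_gene_models()] result.
#' @param config The same [sim_config()].
#' @return Object of class `ground_truth`: data frames `molecules`,
#'   `nuclei`, `psi_true`, plus `pairs` (planted pairs echoed with
#'   realized per-cell-type count tables) and the barcode `whitelist`.
#' @export
generate_molecules <- function(models, config = models$config) {
  stopifnot(inherits(models, "gene_models"))
  with_seed(config$seed + 1L, {
    cts <- config$celltype_names
    n_nuc <- config$n_celltypes * config$nuclei_per_celltype
    nuclei <- data.frame(nucleus_id = sprintf("N%04d", seq_len(n_nuc)),
                         celltype = rep(cts, each = config$nuclei_per_celltype),
                         barcode = random_dna_unique(n_nuc, 16L),
                         stringsAsFactors = FALSE)
    n_mol_per_nuc <- stats::rpois(n_nuc, config$reads_per_nucleus)
    mol <- data.frame(nucleus_id = rep(nuclei$nucleus_id, n_mol_per_nuc),
                      celltype = rep(nuclei$celltype, n_mol_per_nuc),
                      barcode = rep(nuclei$barcode, n_mol_per_nuc),
                      stringsAsFactors = FALSE)
    n_mol <- nrow(mol)
    if (n_mol == 0L) stop("no molecules generated; increase reads_per_nucleus")
    mol$gene_id <- sample(models$genes$gene_id, n_mol, replace = TRUE)
    mol$mol_id <- sprintf("M%06d", seq_len(n_mol))
    mol$tss_var <- NA_integer_; mol$polya_var <- NA_integer_
    incl <- vector("list", n_mol)  # integer vector of included internal slots

    planted_by_gene <- split(config$planted_pairs,
                             vapply(config$planted_pairs, `[[`, "", "gene_id"))
    for (gid in unique(mol$gene_id)) {
      n_slots <- models$genes$n_slots[models$genes$gene_id == gid]
      internal_slots <- if (n_slots > 2L) 2L:(n_slots - 1L) else integer(0)
      pps <- planted_by_gene[[gid]] %||% list()
      planted_slots <- unlist(lapply(pps, `[[`, "exons"))
      if (anyDuplicated(planted_slots))
        stop("gene ", gid, ": a slot appears in more than one planted pair")
      for (ct in cts) {
        idx <- which(mol$gene_id == gid & mol$celltype == ct)
        m <- length(idx)
        if (m == 0L) next
        inc <- matrix(0L, nrow = m, ncol = length(internal_slots),
                      dimnames = list(NULL, as.character(internal_slots)))
        for (s in internal_slots)
          inc[, as.character(s)] <- stats::rbinom(m, 1L, psi_lookup(models, gid, s, ct))
        tssv <- sample.int(config$n_tss, m, replace = TRUE)
        pav <- sample.int(config$n_polya, m, replace = TRUE)
        for (pp in pps) {
          eff_or <- pp$or_by_celltype[ct]
          eff_const <- pp$constitutive_by_celltype[[ct]]
          if (startsWith(pp$kind, "exon_exon")) {
            if (!is.null(eff_const)) {
              el <- eff_const$element %||% 1L
              val <- eff_const$value %||% 1L
              inc[, as.character(pp$exons[el])] <- as.integer(val)
            } else if (!is.na(eff_or) && length(eff_or)) {
              p <- psi_lookup(models, gid, pp$exons, ct)
              d <- draw_biv_bernoulli(m, p[1L], p[2L], eff_or[[1L]])
              inc[, as.character(pp$exons[1L])] <- d[, 1L]
              inc[, as.character(pp$exons[2L])] <- d[, 2L]
            }
          } else {  # end-site pair: element 1 = site usage, element 2 = exon
            n_sites <- if (pp$kind == "tss_exon") config$n_tss else config$n_polya
            if (!is.null(eff_const)) {
              el <- eff_const$element %||% 1L
              val <- eff_const$value %||% 1L
              if (el == 1L) {
                fixed_site <- if (val == 1L) pp$site else
                  setdiff(seq_len(n_sites), pp$site)[1L]
                if (pp$kind == "tss_exon") tssv <- rep(fixed_site, m)
                else pav <- rep(fixed_site, m)
              } else {
                inc[, as.character(pp$exons)] <- as.integer(val)
              }
            } else if (!is.na(eff_or) && length(eff_or)) {
              p2 <- psi_lookup(models, gid, pp$exons, ct)
              d <- draw_biv_bernoulli(m, 1 / n_sites, p2, eff_or[[1L]])
              site_used <- d[, 1L] == 1L
              others <- setdiff(seq_len(n_sites), pp$site)
              alt <- if (length(others)) sample(others, m, replace = TRUE)
              else rep(pp$site, m)
              chosen <- ifelse(site_used, pp$site, alt)
              if (pp$kind == "tss_exon") tssv <- chosen else pav <- chosen
              inc[, as.character(pp$exons)] <- d[, 2L]
            }
          }
        }
        mol$tss_var[idx] <- tssv
        mol$polya_var[idx] <- pav
        incl[idx] <- lapply(seq_len(m), function(i)
          internal_slots[inc[i, ] == 1L])
      }
    }
    mol$incl_slots <- vapply(incl, paste, character(1), collapse = ",")
    mol$tss_id <- sprintf("%s:TSS%d", mol$gene_id, mol$tss_var)
    mol$polya_id <- sprintf("%s:PA%d", mol$gene_id, mol$polya_var)
    # unique UMIs per (barcode, gene): guarantees one molecule per triplet
    mol$umi <- random_dna(n_mol, 12L)
    repeat {
      dup <- duplicated(paste(mol$barcode, mol$umi, mol$gene_id))
      if (!any(dup)) break
      mol$umi[dup] <- random_dna(sum(dup), 12L)
    }
    mol <- mol[, c("mol_id", "nucleus_id", "celltype", "barcode", "umi",
                   "gene_id", "tss_var", "polya_var", "tss_id", "polya_id",
                   "incl_slots")]
    structure(list(molecules = mol, nuclei = nuclei,
                   psi_true = models$psi_spec,
                   pairs = realized_pair_counts(mol, config),
                   whitelist = nuclei$barcode),
              class = "ground_truth")
  })
}

# Echo planted pairs with realized per-cell-type 2x2 counts.
realized_pair_counts <- function(mol, config) {
  out <- list()
  for (k in seq_along(config$planted_pairs)) {
    pp <- config$planted_pairs[[k]]
    sub <- mol[mol$gene_id == pp$gene_id, ]
    slots <- lapply(strsplit(sub$incl_slots, ",", fixed = TRUE), as.integer)
    for (ct in c(config$celltype_names, "pseudo_bulk")) {
      rows <- if (ct == "pseudo_bulk") seq_len(nrow(sub))
      else which(sub$celltype == ct)
      if (startsWith(pp$kind, "exon_exon")) {
        a <- vapply(slots[rows], function(s) pp$exons[1L] %in% s, logical(1))
        b <- vapply(slots[rows], function(s) pp$exons[2L] %in% s, logical(1))
      } else {
        v <- if (pp$kind == "tss_exon") sub$tss_var[rows] else sub$polya_var[rows]
        a <- v == pp$site
        b <- vapply(slots[rows], function(s) pp$exons[1L] %in% s, logical(1))
      }
      out[[length(out) + 1L]] <- data.frame(
        pair = k, gene_id = pp$gene_id, kind = pp$kind, context = ct,
        in_in = sum(a & b), in_out = sum(a & !b),
        out_in = sum(!a & b), out_out = sum(!a & !b),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
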