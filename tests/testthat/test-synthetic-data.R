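# The synthetic generator: model validity, determinism, planted
# effects, noise processes.

test_that("minimal model is valid and counts are as configured", {
  cfg <- sim_config(seed = 1, n_genes = 1, exons_per_gene = 5,
                    n_tss = 1, n_polya = 1)
  m <- generate_gene_models(cfg)
  expect_equal(nrow(m$genes), 1L)
  expect_equal(nrow(m$exons), 5L)
  expect_gte(nrow(m$transcripts), 2L)
  # alternative internal exons are flanked by constitutive first/last
  expect_setequal(unique(m$exons$role), c("first", "internal", "last"))
  expect_equal(sum(m$exons$role == "internal"), 3L)
})

test_that("exons_per_gene below 3 is rejected", {
  expect_error(sim_config(exons_per_gene = 2), "constitutive flanks")
})

test_that("TSS catalog holds one entry per configured variant", {
  cfg <- sim_config(seed = 2, n_genes = 3, n_tss = 2, n_polya = 1)
  m <- generate_gene_models(cfg)
  expect_equal(as.vector(table(m$tss$gene_id)), rep(2L, 3))
  expect_equal(as.vector(table(m$polya$gene_id)), rep(1L, 3))
  # site positions sit at the 5'/3' ends of their exon variants
  plus <- m$genes$gene_id[m$genes$strand == "+"]
  for (g in plus) {
    firsts <- m$exons[m$exons$gene_id == g & m$exons$role == "first", ]
    expect_setequal(m$tss$pos[m$tss$gene_id == g], firsts$start)
  }
})

test_that("identical config yields byte-identical fixtures", {
  cfg <- tiny_config(seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(simulate_fixture(cfg), d1)
  write_fixture(simulate_fixture(tiny_config(seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("realized per-celltype inclusion tracks psi_spec", {
  cfg <- sim_config(seed = 21, n_genes = 1, exons_per_gene = 5,
                    n_celltypes = 2, nuclei_per_celltype = 40,
                    reads_per_nucleus = 50, n_tss = 1,
                    intron_retention_prob = 0,
                    contaminant_fracs = c(unbarcoded = 0, intronic = 0),
                    tag_error_rates = list(sub = 0, ins = 0, del = 0,
                                           region = "tag"),
                    truncation = list(prob = 0, mean = 800, sd = 300))
  m <- generate_gene_models(cfg)
  tr <- generate_molecules(m, cfg)
  mol <- tr$molecules
  for (ct in cfg$celltype_names) {
    sub <- mol[mol$celltype == ct, ]
    for (s in 2:4) {
      p <- m$psi_spec$psi[m$psi_spec$slot == s & m$psi_spec$celltype == ct]
      hit <- vapply(strsplit(sub$incl_slots, ","), function(x)
        s %in% as.integer(x), logical(1))
      ci <- binom.test(sum(hit), length(hit), p)$conf.int
      # wide binomial check at ~2000 molecules per cell type
      expect_true(p >= ci[1] - 0.02 && p <= ci[2] + 0.02,
                  info = sprintf("slot %d in %s: p=%.2f obs=%.2f", s, ct, p,
                                 mean(hit)))
    }
  }
})

test_that("planted odds ratios are realized at depth", {
  psi <- expand.grid(gene_id = "G1", slot = 2:4, celltype = c("EN", "IN"),
                     stringsAsFactors = FALSE)
  psi$psi <- 0.5
  cfg <- sim_config(seed = 31, n_genes = 1, exons_per_gene = 5,
                    n_celltypes = 2, celltype_names = c("EN", "IN"),
                    nuclei_per_celltype = 100, reads_per_nucleus = 50,
                    n_tss = 1, psi_spec = psi,
                    planted_pairs = list(
                      plant_pair("G1", "exon_exon_adjacent", exons = c(2, 3),
                                 or_by_celltype = c(EN = 16, IN = 1))))
  m <- generate_gene_models(cfg)
  tr <- generate_molecules(m, cfg)
  pc <- tr$pairs
  en <- pc[pc$context == "EN", ]
  or_en <- odds_ratio(c(en$in_in, en$in_out, en$out_in, en$out_out))
  expect_gt(en$in_in + en$in_out + en$out_in + en$out_out, 2000)
  # planted log2 OR = 4, Monte-Carlo tolerance at ~2,500 draws
  expect_lt(abs(or_en$log_odds - 4), 0.45)
  inn <- pc[pc$context == "IN", ]
  or_in <- odds_ratio(c(inn$in_in, inn$in_out, inn$out_in, inn$out_out))
  expect_lt(abs(or_in$log_odds), 0.3)
})

test_that("constitutive flag forces the element in that cell type", {
  cfg <- sim_config(seed = 8, n_genes = 1, exons_per_gene = 5,
                    n_celltypes = 2, celltype_names = c("A", "B"),
                    nuclei_per_celltype = 10, reads_per_nucleus = 20,
                    n_tss = 1,
                    planted_pairs = list(
                      plant_pair("G1", "exon_exon_adjacent", exons = c(2, 3),
                                 constitutive_by_celltype = list(
                                   A = list(element = 1, value = 1)))))
  tr <- generate_molecules(generate_gene_models(cfg), cfg)
  a <- tr$molecules[tr$molecules$celltype == "A", ]
  expect_true(all(vapply(strsplit(a$incl_slots, ","), function(x)
    2L %in% as.integer(x), logical(1))))
})

test_that("odds ratio and constitutive flag cannot share a cell type", {
  expect_error(plant_pair("G1", "exon_exon_adjacent", exons = c(2, 3),
                          or_by_celltype = c(A = 4),
                          constitutive_by_celltype = list(A = list())),
               "mutually exclusive")
})

test_that("contaminant classes arise at the configured fractions", {
  cfg <- sim_config(seed = 13, n_genes = 2, exons_per_gene = 5,
                    nuclei_per_celltype = 60, reads_per_nucleus = 45,
                    contaminant_fracs = c(unbarcoded = 0.3, intronic = 0.2))
  sim <- simulate_fixture(cfg)
  n <- nrow(sim$emitted$link)
  tab <- table(sim$emitted$link$class)
  expect_gt(n, 8000)
  # binomial: ~3 sigma bands
  for (cl in c("unbarcoded", "intronic")) {
    p <- unname(cfg$contaminant_fracs[[cl]])
    expect_lt(abs(tab[[cl]] / n - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
  # every read traces to a molecule; contaminants are flagged
  expect_true(all(sim$emitted$link$mol_id %in% sim$truth$molecules$mol_id))
  # intronic contaminant blocks avoid all annotated exons
  intr <- sim$emitted$reads[sim$emitted$link$class == "intronic", ]
  expect_equal(on_target_rate(intr, sim$models$exons), 0)
})

test_that("zero tag noise emits ground-truth 28-mers verbatim", {
  sim <- cached_fixture("tiny", function() simulate_fixture(tiny_config()))
  link <- sim$emitted$link
  mol <- sim$truth$molecules[match(link$mol_id, sim$truth$molecules$mol_id), ]
  expect_equal(substr(sim$emitted$tags$tag_region, 13L, 40L),
               paste0(mol$barcode, mol$umi))
})

test_that("retention probability one removes fully spliced reads", {
  cfg <- tiny_config(seed = 17, intron_retention_prob = 1)
  sim <- simulate_fixture(cfg)
  nblocks <- vapply(parse_blocks(sim$emitted$reads$blocks), nrow, integer(1))
  expect_true(all(nblocks == 1L))
})

test_that("fixture round-trips through disk exactly", {
  sim <- cached_fixture("tiny", function() simulate_fixture(tiny_config()))
  d <- tempfile()
  write_fixture(sim, d)
  fx <- read_fixture(d)
  expect_equal(fx$reads$blocks, sim$emitted$reads$blocks)
  expect_equal(fx$reads$start, sim$emitted$reads$start)
  expect_equal(attr(fx$reads, "n_rejected"), 0L)
  expect_setequal(fx$whitelist, sim$emitted$whitelist)
  # GTF (1-based) -> internal (0-based half-open) conversion is exact
  ann <- fx$models
  key0 <- sort(paste(sim$models$exons$gene_id, sim$models$exons$start,
                     sim$models$exons$end))
  key1 <- sort(unique(paste(ann$exons$gene_id, ann$exons$start,
                            ann$exons$end)))
  expect_equal(key1, key0[!duplicated(key0)])
  unlink(d, recursive = TRUE)
})

test_that("BED12 and GTF agree on transcript structure", {
  sim <- cached_fixture("tiny", function() simulate_fixture(tiny_config()))
  d <- tempfile()
  write_fixture(sim, d)
  gtf <- read_annotation(file.path(d, "annotation.gtf"))
  bed <- read_annotation(file.path(d, "annotation.bed12.bed"))
  for (tid in gtf$transcripts$transcript_id) {
    eg <- merge(gtf$transcript_exons[gtf$transcript_exons$transcript_id == tid, ],
                gtf$exons, by = "exon_id")
    eb <- merge(bed$transcript_exons[bed$transcript_exons$transcript_id == tid, ],
                bed$exons, by = "exon_id")
    expect_equal(sort(paste(eg$start, eg$end)), sort(paste(eb$start, eb$end)),
                 info = tid)
  }
  unlink(d, recursive = TRUE)
})
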