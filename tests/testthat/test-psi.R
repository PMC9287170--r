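# Exon support counting, PSI formulas, filters, variability, disease
# comparison.

# Reads over hand_models(): exons at 0-100, 500-600, 1000-1100,
# 1500-1600 on "+". The middle exons are the alternatives.
exon2 <- function() list(exon_id = "GX:E2", gene_id = "GX", chrom = "chrS",
                         start = 500L, end = 600L, strand = "+")

incl_read <- function(id) hand_read(id, cbind(c(0L, 500L, 1500L),
                                              c(100L, 600L, 1600L)))
skip_read <- function(id) hand_read(id, cbind(c(0L, 1500L),
                                              c(100L, 1600L)))

test_that("support counting applies junction and flank rules", {
  rds <- rbind(incl_read("a1"), incl_read("a2"), skip_read("s1"))
  sup <- count_exon_support(exon2(), rds)
  expect_equal(unname(sup[c("X_in", "X_out", "X_tot")]), c(2L, 1L, 3L))
  # skip read with only 30 bases on one side is not X_out
  thin <- hand_read("s2", cbind(c(70L, 1500L), c(100L, 1600L)))
  sup <- count_exon_support(exon2(), rbind(incl_read("a1"), thin))
  expect_equal(unname(sup["X_out"]), 0L)
  expect_equal(unname(sup["X_tot"]), 2L)  # span still overlaps
  # read splicing into the acceptor and ending inside the exon
  accin <- hand_read("p1", cbind(c(0L, 500L), c(100L, 560L)))
  sup <- count_exon_support(exon2(), rbind(incl_read("a1"), accin))
  expect_equal(unname(sup["X_acc_in"]), 1L)
  # mirrored: read starting inside the exon, splicing out the donor
  donin <- hand_read("p2", cbind(c(540L, 1500L), c(600L, 1600L)))
  sup <- count_exon_support(exon2(), rbind(incl_read("a1"), donin))
  expect_equal(unname(sup["X_don_in"]), 1L)
  # on "-" strand the same geometry maps to the opposite site
  donin_m <- donin; donin_m$strand <- "-"
  em <- exon2(); em$strand <- "-"
  sup <- count_exon_support(em, donin_m)
  expect_equal(unname(sup["X_acc_in"]), 1L)
})

test_that("all three PSI values follow the printed formulas", {
  psi <- compute_psi(c(X_in = 8, X_acc_in = 1, X_don_in = 1, X_out = 10,
                       X_tot = 25))
  expect_equal(unname(psi["psi_overall"]), 0.5)
  expect_equal(unname(psi["psi_acceptor"]), 9 / 19)
  expect_equal(unname(psi["psi_donor"]), 9 / 19)
  psi <- compute_psi(c(X_in = 3, X_acc_in = 0, X_don_in = 0, X_out = 0,
                       X_tot = 3))
  expect_equal(unname(psi), c(1, 1, 1))
  psi <- compute_psi(c(X_in = 0, X_acc_in = 0, X_don_in = 0, X_out = 5,
                       X_tot = 5))
  expect_equal(unname(psi), c(0, 0, 0))
  psi <- compute_psi(c(X_in = 0, X_acc_in = 0, X_don_in = 0, X_out = 0,
                       X_tot = 2))
  expect_true(all(is.na(psi)))
})

test_that("adding a skipping UMI strictly lowers every PSI", {
  set.seed(31)
  for (i in 1:25) {
    s <- c(X_in = rpois(1, 10) + 1, X_acc_in = rpois(1, 2),
           X_don_in = rpois(1, 2), X_out = rpois(1, 5), X_tot = 40)
    p0 <- compute_psi(s)
    s["X_out"] <- s["X_out"] + 1
    p1 <- compute_psi(s)
    expect_true(all(p1 < p0))
  }
})

test_that("alternative-exon filter enforces every printed rule", {
  base <- data.frame(exon_id = "e", context = "pseudo_bulk", X_in = 50L,
                     X_out = 50L, X_acc_in = 0L, X_don_in = 0L, X_tot = 100L,
                     psi_overall = 0.5, psi_acceptor = 0.5, psi_donor = 0.5,
                     annotated = TRUE, n_annot_sites = 2L,
                     nonexonic_bases = 0L)
  expect_equal(nrow(filter_alternative_exons(base)), 1L)
  # PSI outside [0.05, 0.95]
  hi <- transform(base, psi_overall = 0.97)
  expect_equal(nrow(filter_alternative_exons(hi)), 0L)
  edge <- transform(base, psi_overall = 0.95, psi_donor = 0.05)
  expect_equal(nrow(filter_alternative_exons(edge)), 1L)  # inclusive
  # coverage ratio boundary: 0.79 fails, 0.80 passes
  low <- transform(base, X_tot = round(100 / 0.79))
  expect_equal(nrow(filter_alternative_exons(low)), 0L)
  ok <- transform(base, X_tot = 125L)
  expect_equal(nrow(filter_alternative_exons(ok)), 1L)
  # novel exon with an annotated acceptor and 80 non-exonic bases is
  # excluded as an intron-retention / alternative-site event
  nov <- transform(base, annotated = FALSE, n_annot_sites = 1L,
                   nonexonic_bases = 80L)
  expect_equal(nrow(filter_alternative_exons(nov)), 0L)
  nov2 <- transform(base, annotated = FALSE, n_annot_sites = 1L,
                    nonexonic_bases = 60L)
  expect_equal(nrow(filter_alternative_exons(nov2)), 1L)
})

test_that("cell-type PSI applies the depth-10 rule exactly", {
  long <- data.frame(exon_id = "e1",
                     context = c("A", "B"),
                     X_in = c(9L, 10L), X_out = 0L, X_acc_in = 0L,
                     X_don_in = 0L, X_tot = c(9L, 10L),
                     psi_overall = 1, psi_acceptor = 1, psi_donor = 1)
  wide <- celltype_psi(long)
  expect_true(is.na(wide$A))
  expect_equal(wide$B, 1)
})

test_that("variability arithmetic and categories are exact", {
  w <- data.frame(exon_id = c("e1", "e2", "e3", "e4"),
                  A = c(0.9, 0.5, NA, 0.2),
                  B = c(0.1, 0.5, 0.4, 0.5),
                  C = c(0.5, 0.5, 0.7, NA),
                  D = c(0.5, 0.5, 0.45, NA))
  v <- psi_variability(w)
  expect_equal(v$variability, c(0.8, 0, 0.3, 0.3))
  expect_equal(v$category, c("high", "low", "mid", "mid"))
  # fewer than two informative cell types -> NA record
  w1 <- data.frame(exon_id = "e", A = 0.5, B = NA_real_)
  expect_true(is.na(psi_variability(w1)$variability))
})

test_that("quadrant labels cut at 0.5 with inclusive-upward boundary", {
  expect_equal(novel_exon_quadrants(0.8, 0.7),
               "high_inclusion/high_variability")
  expect_equal(novel_exon_quadrants(0.5, 0.5),
               "high_inclusion/high_variability")
  expect_equal(novel_exon_quadrants(0.1, 0.1),
               "low_inclusion/low_variability")
  expect_true(is.na(novel_exon_quadrants(NA, 0.3)))
})

test_that("rank-sum comparison matches exact enumeration", {
  # {1,2,3} vs {4,5,6}: most extreme of choose(6,3)=20 orderings,
  # two-sided exact p = 2/20 = 0.1
  res <- compare_disease_exons(c(1, 2, 3, 4, 5, 6),
                               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$fold_ratio, 2 / 5)
})

test_that("a planted variability shift is detected", {
  set.seed(41)
  other <- runif(500, 0, 0.5)
  disease <- runif(50, 0, 0.5) + 0.4
  res <- compare_disease_exons(c(disease, other),
                               c(rep(TRUE, 50), rep(FALSE, 500)))
  expect_lt(res$p_value, 0.001)
  expect_gt(res$fold_ratio, 1.5)
  # null behavior: same distribution, moderate p
  resn <- compare_disease_exons(runif(550), c(rep(TRUE, 50), rep(FALSE, 500)))
  expect_gt(resn$p_value, 0.001)
})

test_that("microexon exclusion drops short exons before testing", {
  v <- c(0.9, 0.8, 0.1, 0.2)
  dis <- c(TRUE, TRUE, FALSE, FALSE)
  len <- c(20, 100, 100, 100)
  res <- compare_disease_exons(v, dis, exon_length = len,
                               exclude_microexons = TRUE)
  expect_equal(res$n_disease, 1L)
})

test_that("gene expression variability is max minus min, NAs ignored", {
  m <- rbind(G1 = c(1, 3.5, 2), G2 = c(2, 2, 2), G3 = c(1, NA, 4))
  colnames(m) <- c("A", "B", "C")
  v <- gene_expression_variability(m, c("G1", "G2", "G3", "G4"))
  expect_equal(unname(v[1:3]), c(2.5, 0, 3))
  expect_true(is.na(v["G4"]))
})

test_that("planted PSI is recovered within binomial intervals", {
  sim <- cached_fixture("mid", function()
    simulate_fixture(tiny_config(seed = 23, n_genes = 2,
                                 nuclei_per_celltype = 30,
                                 reads_per_nucleus = 40)))
  mols <- sim$truth$molecules
  reads <- sim$emitted$reads
  reads$celltype <- mols$celltype[match(sim$emitted$link$mol_id, mols$mol_id)]
  ex <- discover_internal_exons(reads, sim$models)
  pt <- psi_table(ex, reads, contexts = "pseudo_bulk")
  pt <- merge(pt, ex, by = "exon_id")
  ann <- merge(pt[pt$annotated, ], sim$models$exons,
               by = c("gene_id", "chrom", "start", "end", "strand"))
  psi_true <- sim$models$psi_spec
  n_cover <- 0L; n_tot <- 0L
  for (i in seq_len(nrow(ann))) {
    if (ann$role[i] != "internal") next
    p <- mean(psi_true$psi[psi_true$gene_id == ann$gene_id[i] &
                             psi_true$slot == ann$slot[i]])
    k <- ann$X_in[i] + ann$X_acc_in[i] + ann$X_don_in[i]
    nn <- k + ann$X_out[i]
    ci <- binom.test(k, nn)$conf.int
    n_tot <- n_tot + 1L
    if (p >= ci[1] && p <= ci[2]) n_cover <- n_cover + 1L
  }
  expect_gte(n_tot, 6L)
  expect_gte(n_cover / n_tot, 0.8)
})
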