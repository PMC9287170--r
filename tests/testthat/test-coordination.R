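# Exon-pair coordination: adjacency, pair tables, testing, selection,
# tracing, enrichment, conservation.

test_that("pair enumeration classifies adjacency by intervening exons", {
  alt <- data.frame(exon_id = c("GX:E2", "GX:E3"), gene_id = "GX",
                    start = c(500L, 1000L), end = c(600L, 1100L))
  m <- hand_models()
  p <- enumerate_pairs(alt, m)
  expect_equal(nrow(p), 1L)
  expect_equal(p$adjacency, "adjacent")
  # insert an annotated exon between them
  m2 <- hand_models(exon_starts = c(0L, 500L, 750L, 1000L, 1500L),
                    exon_ends = c(100L, 600L, 800L, 1100L, 1600L))
  alt2 <- data.frame(exon_id = c("GX:E2", "GX:E4"), gene_id = "GX",
                     start = c(500L, 1000L), end = c(600L, 1100L))
  expect_equal(enumerate_pairs(alt2, m2)$adjacency, "distant")
  # three alternative exons give choose(3, 2) pairs
  alt3 <- data.frame(exon_id = c("a", "b", "c"), gene_id = "GX",
                     start = c(500L, 1000L, 1200L),
                     end = c(600L, 1100L, 1300L))
  expect_equal(nrow(enumerate_pairs(alt3, m)), 3L)
})

test_that("pair tables require a determinate call for both exons", {
  e2 <- list(start = 500L, end = 600L, strand = "+")
  e3 <- list(start = 1000L, end = 1100L, strand = "+")
  both_in <- hand_read("r1", cbind(c(0L, 500L, 1000L, 1500L),
                                   c(100L, 600L, 1100L, 1600L)))
  both_out <- hand_read("r2", cbind(c(0L, 1500L), c(100L, 1600L)))
  in_out <- hand_read("r3", cbind(c(0L, 500L, 1500L),
                                  c(100L, 600L, 1600L)))
  # determinate for exon 2 only: ends inside exon 3
  partial <- hand_read("r4", cbind(c(0L, 500L, 1000L),
                                   c(100L, 600L, 1050L)))
  rds <- rbind(both_in, both_in, both_out, in_out, partial)
  cnt <- build_pair_counts(e2, e3, rds)
  expect_equal(unname(cnt), c(2L, 1L, 0L, 1L))
})

test_that("test_pair produces chi-squared results and effect sizes", {
  r <- test_pair(c(in_in = 50, in_out = 5, out_in = 5, out_out = 50))
  expect_lt(r$p_value, 1e-10)
  expect_equal(r$direction, "mutual_inclusion")
  expect_equal(r$co_inclusion, 50 / 110)
  expect_equal(r$inclusion_ratio, 0.5)
  # perfect independence
  r <- test_pair(c(in_in = 10, in_out = 10, out_in = 10, out_out = 10))
  expect_equal(r$p_value, 1)
  expect_equal(r$log_odds, 0)
  # shallow table is not testable
  r <- test_pair(c(in_in = 7, in_out = 5, out_in = 5, out_out = 3))
  expect_equal(r$testability, "constitutive")
  expect_true(is.na(r$p_value))
})

test_that("chi-squared p agrees with the reference on random testable tables", {
  set.seed(77)
  n_checked <- 0
  while (n_checked < 200) {
    cnt <- rpois(4, sample(c(8, 15, 40), 1))
    M <- matrix(cnt, 2, 2, byrow = TRUE)
    if (chi2_criterion(M)$class != "testable") next
    r <- test_pair(c(in_in = cnt[1], in_out = cnt[2], out_in = cnt[3],
                     out_out = cnt[4]))
    ref <- suppressWarnings(chisq.test(M, correct = FALSE))
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
})

test_that("one pair per gene: significance and conservation modes", {
  res <- data.frame(pair_id = c("p1", "p2", "p3"),
                    gene_id = c("G1", "G1", "G2"),
                    fdr = c(0.01, 0.2, 0.9),
                    log_odds = c(3, 0.2, 1))
  one <- select_one_per_gene(res)
  expect_equal(one$pair_id, c("p1", "p3"))
  cons <- select_one_per_gene(res, mode = "conservation")
  expect_equal(cons$pair_id, c("p2", "p3"))
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # exhaustive two-sided Fisher p for table (8,2 / 2,8): sum of
  # probabilities of tables at least as extreme under fixed margins
  enum_p <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    p_obs <- dhyper(a, m, n, k)
    sum(vapply(max(0, k - n):min(k, m), function(x) {
      p <- dhyper(x, m, n, k)
      if (p <= p_obs + 1e-12) p else 0
    }, numeric(1)))
  }
  in_pair <- rep(c(TRUE, FALSE), c(10, 10))
  disease <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  res <- disease_pair_enrichment(in_pair, disease)
  expect_equal(res$p_value, enum_p(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(res$p_value, fisher.test(table(in_pair, disease))$p.value,
               tolerance = 1e-12)
  # empty margin
  expect_true(is.na(disease_pair_enrichment(rep(TRUE, 5),
                                            rep(FALSE, 5))$p_value))
})

test_that("planted enrichment is detected, null p is calm", {
  set.seed(5)
  n <- 500
  in_pair <- runif(n) < 0.2
  disease <- ifelse(in_pair, runif(n) < 0.5, runif(n) < 0.1)
  expect_lt(disease_pair_enrichment(in_pair, disease)$p_value, 0.01)
  ps <- replicate(50, {
    disease_pair_enrichment(runif(n) < 0.2, runif(n) < 0.2)$p_value
  })
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("conservation correlation behaves on edge cases", {
  res <- data.frame(exon1 = c("a", "b", "c"), exon2 = c("d", "e", "f"),
                    log_odds = c(1, 2, 3), inclusion_ratio = c(0.2, 0.5, 0.8))
  # identical scores -> zero variance -> NA
  sc <- setNames(rep(0.5, 6), c("a", "b", "c", "d", "e", "f"))
  expect_true(is.na(conservation_vs_coordination(res, sc)$r))
  # noiseless linear relation -> r = 1
  sc <- setNames(c(0.1, 0.2, 0.3, 0.9, 0.9, 0.9),
                 c("a", "b", "c", "d", "e", "f"))
  expect_equal(conservation_vs_coordination(res, sc)$r, 1)
})

test_that("a planted weak correlation is recovered at scale", {
  set.seed(61)
  n <- 280
  score <- runif(n)
  lor <- 0.5 + 0.6 * score + rnorm(n, 0, 0.85)  # r ~ 0.2
  res <- data.frame(exon1 = sprintf("a%d", 1:n), exon2 = sprintf("b%d", 1:n),
                    log_odds = lor, inclusion_ratio = runif(n))
  sc <- setNames(c(score, rep(1, n)), c(res$exon1, res$exon2))
  out <- conservation_vs_coordination(res, sc, grouped = TRUE)
  expect_lt(abs(out$r - 0.2), 0.12)
  expect_lt(out$p_value, 0.05)
  expect_false(is.na(out$group_p_lor))
})

test_that("null simulation keeps the significant fraction at bay", {
  set.seed(101)
  n_pairs <- 800
  p <- numeric(0); lor <- numeric(0)
  for (i in seq_len(n_pairs)) {
    d1 <- rbinom(100, 1, 0.5) == 1
    d2 <- rbinom(100, 1, 0.5) == 1
    cnt <- c(in_in = sum(d1 & d2), in_out = sum(d1 & !d2),
             out_in = sum(!d1 & d2), out_out = sum(!d1 & !d2))
    r <- test_pair(cnt)
    p <- c(p, r$p_value); lor <- c(lor, r$log_odds)
  }
  fdr <- adjust_fdr_by(p)
  frac <- mean(!is.na(fdr) & fdr <= 0.05 & abs(lor) >= 1)
  expect_lte(frac, 0.05)
})

test_that("cell-type tracing separates planted classes", {
  psi <- expand.grid(gene_id = "G1", slot = 2:4,
                     celltype = c("A", "B"), stringsAsFactors = FALSE)
  psi$psi <- 0.5
  cfg <- tiny_config(seed = 71, n_genes = 1, n_celltypes = 2,
                     celltype_names = c("A", "B"),
                     nuclei_per_celltype = 40, reads_per_nucleus = 40,
                     n_tss = 1, psi_spec = psi,
                     planted_pairs = list(
                       plant_pair("G1", "exon_exon_adjacent", exons = c(2, 3),
                                  or_by_celltype = c(A = 24, B = 1))))
  sim <- simulate_fixture(cfg)
  mols <- sim$truth$molecules
  reads <- sim$emitted$reads
  reads$celltype <- mols$celltype[match(sim$emitted$link$mol_id, mols$mol_id)]
  ex <- discover_internal_exons(reads, sim$models)
  pt <- merge(psi_table(ex, reads, contexts = "pseudo_bulk"), ex,
              by = "exon_id")
  alt <- filter_alternative_exons(pt)
  pairs <- enumerate_pairs(alt, sim$models)
  res <- test_pairs(pairs, ex, reads)
  planted <- res[res$pair_id == paste(ex$exon_id[ex$start == sort(ex$start)[2]],
                                      ex$exon_id[ex$start == sort(ex$start)[3]],
                                      sep = "|"), ]
  tr <- trace_pair_to_celltypes(res[res$significant, ], ex, reads)
  trA <- tr[tr$celltype == "A", ]
  expect_true(any(trA$class == "significant_same"))
  trB <- tr[tr$celltype == "B", ]
  expect_true(all(trB$class %in% c("not_significant", "low_counts",
                                   "constitutive")))
})
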