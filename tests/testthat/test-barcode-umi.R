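# Tag matching, the correction cascade, deduplication.

mutate_at <- function(tag, pos, to = NULL) {
  ch <- strsplit(tag, "")[[1]]
  for (p in pos) {
    ch[p] <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), ch[p])[1] else to
  }
  paste0(ch, collapse = "")
}

test_that("tag reference groups and deduplicates per gene", {
  tags <- data.frame(gene_id = c("G1", "G1", "G2"),
                     tag = c(strrep("A", 28), strrep("C", 28),
                             strrep("G", 28)), stringsAsFactors = FALSE)
  ref <- build_tag_reference(tags)
  expect_equal(lengths(ref[c("G1", "G2")]), c(G1 = 2L, G2 = 1L))
  # duplicate within a gene collapses; same tag in two genes stays in both
  tags2 <- data.frame(gene_id = c("G1", "G1", "G2"),
                      tag = rep(strrep("A", 28), 3))
  ref2 <- build_tag_reference(tags2)
  expect_equal(lengths(ref2[c("G1", "G2")]), c(G1 = 1L, G2 = 1L))
  expect_equal(ref2$G1, ref2$G2)
})

test_that("malformed tags are rejected with a count", {
  tags <- data.frame(gene_id = c("G1", "G1", "G1"),
                     tag = c(strrep("A", 28), strrep("A", 27),
                             paste0(strrep("N", 28))))
  expect_warning(ref <- build_tag_reference(tags), "2 malformed")
  expect_equal(attr(ref, "n_rejected"), 2L)
  expect_equal(lengths(ref["G1"]), c(G1 = 1L))
})

test_that("sliding-window match applies the 22/28 mismatch rule", {
  set.seed(5)
  tag <- random_dna(1, 28)
  ref <- build_tag_reference(data.frame(gene_id = "G1", tag = tag))
  embed <- function(t) paste0(random_dna(1, 9), t, random_dna(1, 15))
  # exact hit
  m <- match_ont_tag(embed(tag), "G1", ref)
  expect_equal(m$status, "matched")
  expect_equal(m$mismatches, 0L)
  expect_equal(m$tag, tag)
  # 1 mismatch at position 5 plus 1 at 25: 1 in the first 22, 2 total
  m <- match_ont_tag(embed(mutate_at(tag, c(5, 25))), "G1", ref)
  expect_equal(m$status, "matched")
  expect_equal(m$mismatches, 2L)
  # 2 mismatches at positions 3 and 10: 2 in the first 22 -> rejected
  m <- match_ont_tag(embed(mutate_at(tag, c(3, 10))), "G1", ref)
  expect_equal(m$status, "unmatched")
  # 3 total mismatches -> rejected
  m <- match_ont_tag(embed(mutate_at(tag, c(5, 24, 27))), "G1", ref)
  expect_equal(m$status, "unmatched")
  # absent gene
  expect_equal(match_ont_tag(embed(tag), "G9", ref)$status, "no_reference")
})

test_that("a best-score tie between distinct references is ambiguous", {
  t1 <- paste0(strrep("A", 27), "C")
  t2 <- paste0(strrep("A", 27), "G")
  ref <- build_tag_reference(data.frame(gene_id = c("G1", "G1"),
                                        tag = c(t1, t2)))
  probe <- paste0(strrep("T", 6), strrep("A", 28), strrep("T", 6))
  # both references at 1 mismatch
  expect_equal(match_ont_tag(probe, "G1", ref)$status, "ambiguous")
})

test_that("correction cascade follows the LevD rules", {
  set.seed(9)
  t1 <- random_dna(1, 28)
  ref <- build_tag_reference(data.frame(gene_id = "G1", tag = t1))
  # LevD = 0 -> illumina_confirmed
  r <- correct_umis(data.frame(gene_id = "G1", tag = t1, count = 5), ref)
  expect_equal(r$status, "illumina_confirmed")
  expect_equal(r$levd, 0L)
  # LevD = 2, corrected triplet unseen -> corrected and rewritten
  t2 <- mutate_at(t1, c(3, 17))
  r <- correct_umis(data.frame(gene_id = "G1", tag = t2, count = 1), ref)
  expect_equal(r$status, "corrected")
  expect_equal(r$tag, t1)
  expect_equal(r$levd, 2L)
  # LevD = 2 but the corrected triplet was already accepted -> merged
  r <- correct_umis(data.frame(gene_id = "G1", tag = c(t1, t2),
                               count = c(9, 1)), ref)
  expect_equal(r$status, c("illumina_confirmed", "merged"))
  # LevD = 3 -> discarded by default, routed on request
  t3 <- mutate_at(t1, c(2, 9, 20))
  r <- correct_umis(data.frame(gene_id = "G1", tag = t3, count = 1), ref)
  expect_equal(r$status, "discarded")
  expect_equal(attr(r, "case_counts")[["discarded_levd3"]], 1L)
  r <- correct_umis(data.frame(gene_id = "G1", tag = t3, count = 1), ref,
                    route_levd3 = TRUE)
  expect_equal(r$status, "novel")
})

test_that("far tags become novel or merge by accepted-tag distance", {
  set.seed(11)
  t1 <- random_dna(1, 28)
  far <- random_dna(1, 28)  # LevD >> 3 from t1 almost surely
  stopifnot(utils::adist(t1, far) > 6)
  ref <- build_tag_reference(data.frame(gene_id = "G1", tag = t1))
  # alone: novel (no accepted tags nearby)
  r <- correct_umis(data.frame(gene_id = "G1", tag = far, count = 1), ref)
  expect_equal(r$status, "novel")
  # processed after an accepted twin at distance 1 -> merged into it
  far2 <- mutate_at(far, 7)
  r <- correct_umis(data.frame(gene_id = "G1", tag = c(far, far2),
                               count = c(5, 1)), ref)
  expect_equal(r$status, c("novel", "merged"))
  expect_equal(r$tag[2], far)
  # mid-distance (3-5) to accepted: discarded by default
  far3 <- mutate_at(far, c(2, 10, 15, 21))
  stopifnot(utils::adist(far, far3) %in% 3:5)
  r <- correct_umis(data.frame(gene_id = "G1", tag = c(far, far3),
                               count = c(5, 1)), ref)
  expect_equal(r$status[2], "discarded")
  expect_equal(attr(r, "case_counts")[["discarded_mid"]], 1L)
})

test_that("correction is idempotent and never inflates molecules", {
  sim <- cached_fixture("tiny", function() simulate_fixture(tiny_config()))
  ref <- build_tag_reference(sim$emitted$illumina_tags)
  mol <- sim$truth$molecules
  cand <- data.frame(gene_id = mol$gene_id,
                     tag = paste0(mol$barcode, mol$umi), count = 1L)
  r1 <- correct_umis(cand, ref)
  r2 <- correct_umis(r1[, c("gene_id", "tag")] |>
                       transform(count = 1L), ref)
  expect_equal(r2$tag, r1$tag)
  expect_true(all(r2$status == "illumina_confirmed"))
  accepted <- sum(r1$status %in% c("illumina_confirmed", "corrected", "novel"))
  expect_lte(accepted, nrow(unique(cand[c("gene_id", "tag")])))
})

test_that("deduplication keeps the longest span, then smallest id", {
  rec <- data.frame(read_id = c("r3", "r1", "r2", "r9"),
                    barcode = "B", umi = "U", gene_id = "G1",
                    span = c(100, 200, 200, 50))
  out <- deduplicate_molecules(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_id, "r1")
  expect_equal(out$n_reads, 4L)
  # distinct UMIs stay distinct
  rec$umi <- paste0("U", 1:4)
  expect_equal(nrow(deduplicate_molecules(rec)), 4L)
})

test_that("exact barcode detection is strict", {
  set.seed(21)
  wl <- random_dna_unique(5, 16)
  read <- paste0(random_dna(1, 10), wl[2], random_dna(1, 10))
  expect_equal(as.character(exact_barcode_detect(read, wl)), wl[2])
  # one mismatch fails on this path
  read1 <- paste0(random_dna(1, 10), mutate_at(wl[2], 8), random_dna(1, 10))
  hit <- exact_barcode_detect(read1, wl)
  expect_true(is.na(hit))
  # two embedded barcodes are ambiguous
  read2 <- paste0(wl[1], wl[3])
  expect_equal(attr(exact_barcode_detect(read2, wl), "status"), "ambiguous")
})

test_that("zero-noise pipeline recovers the planted molecules exactly", {
  sim <- cached_fixture("tiny", function() simulate_fixture(tiny_config()))
  ref <- build_tag_reference(sim$emitted$illumina_tags)
  mols <- process_tags(sim$emitted$reads, sim$emitted$tags, ref)
  truth_key <- sort(paste(sim$truth$molecules$barcode,
                          sim$truth$molecules$umi,
                          sim$truth$molecules$gene_id))
  got_key <- sort(paste(mols$barcode, mols$umi, mols$gene_id))
  expect_equal(got_key, truth_key)
  expect_true(all(mols$status == "illumina_confirmed"))
})

test_that("barcode detection rate is total on a zero-noise fixture", {
  sim <- cached_fixture("tiny", function() simulate_fixture(tiny_config()))
  hits <- vapply(seq_len(nrow(sim$emitted$tags)), function(i)
    !is.na(exact_barcode_detect(sim$emitted$tags$tag_region[i],
                                sim$emitted$whitelist)), logical(1))
  expect_equal(mean(hits), 1)
})
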