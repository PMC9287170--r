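# Matching noisy long-read barcode-UMI tags to a short-read reference
# and collapsing reads to unique molecules.

#' Build the per-gene short-read tag reference
#'
#' Groups Illumina-derived barcode-UMI 28-mers by gene into
#' deduplicated reference sets. Malformed tags (wrong length or
#' alphabet) are dropped with a warning count.
#'
#' @param illumina_tags Data frame with `gene_id` and either a 28-nt
#'   `tag` column or 16-nt `barcode` + 12-nt `umi` columns.
#' @return Object of class `tag_reference`: a named list mapping gene
#'   id to a sorted character vector of 28-mers; attribute
#'   `n_rejected` counts dropped records.
#' @export
build_tag_reference <- function(illumina_tags) {
  tag <- if ("tag" %in% names(illumina_tags)) illumina_tags$tag
  else paste0(illumina_tags$barcode, illumina_tags$umi)
  ok <- nchar(tag) == 28L & is_dna(tag)
  if (any(!ok)) warning(sum(!ok), " malformed tag(s) rejected")
  ref <- lapply(split(tag[ok], illumina_tags$gene_id[ok]),
                function(x) sort(unique(x)))
  structure(ref, class = "tag_reference", n_rejected = sum(!ok))
}

# Batched sliding-window matcher for one gene's reference set.
# A reference 28-mer matches a window iff Hamming mismatches <= 1 in
# positions 1-22 AND <= 2 in positions 1-28; per read the unique
# best-scoring reference wins, ties across distinct references are
# ambiguous. Returns a data frame (tag, observed, mismatches, status).
match_tags_batch <- function(tagseqs, tags_ref, max_scan = 200L,
                             chunk = 4000L) {
  n <- length(tagseqs)
  out <- data.frame(tag = rep(NA_character_, n),
                    observed = rep(NA_character_, n),
                    mismatches = rep(NA_integer_, n),
                    status = rep("unmatched", n),
                    stringsAsFactors = FALSE)
  if (n == 0L || !length(tags_ref)) {
    out$status <- rep("no_reference", n)
    return(out)
  }
  oh_ref <- dna_onehot(tags_ref, 28L)
  regions <- substr(tagseqs, 1L, max_scan)
  nwin <- pmax(0L, nchar(regions) - 27L)
  ridx <- rep(seq_len(n), nwin)
  wstart <- unlist(lapply(nwin, seq_len), use.names = FALSE)
  win <- substring(regions[ridx], wstart, wstart + 27L)
  total <- length(win)
  best_mm <- rep(Inf, n); best_ref <- rep(NA_integer_, n)
  best_win <- rep(NA_integer_, n); tie <- rep(FALSE, n)
  s <- 1L
  while (s <= total) {
    e <- min(s + chunk - 1L, total)
    w_oh <- dna_onehot(win[s:e], 28L)
    m28 <- 28 - crossprod(oh_ref, w_oh)
    m22 <- 22 - crossprod(oh_ref[seq_len(88L), , drop = FALSE],
                          w_oh[seq_len(88L), , drop = FALSE])
    vi <- which(m28 <= 2 & m22 <= 1, arr.ind = TRUE)
    if (nrow(vi)) {
      mm <- m28[vi]
      wglob <- s + vi[, 2L] - 1L
      rd <- ridx[wglob]
      for (k in seq_along(mm)) {
        r <- rd[k]
        if (mm[k] < best_mm[r]) {
          best_mm[r] <- mm[k]; best_ref[r] <- vi[k, 1L]
          best_win[r] <- wglob[k]; tie[r] <- FALSE
        } else if (mm[k] == best_mm[r] && vi[k, 1L] != best_ref[r]) {
          tie[r] <- TRUE
        }
      }
    }
    s <- e + 1L
  }
  hit <- is.finite(best_mm) & !tie
  out$status[tie & is.finite(best_mm)] <- "ambiguous"
  out$tag[hit] <- tags_ref[best_ref[hit]]
  out$observed[hit] <- win[best_win[hit]]
  out$mismatches[hit] <- as.integer(best_mm[hit])
  out$status[hit] <- "matched"
  out
}

#' Match a noisy read tag against the gene's reference set
#'
#' Scans every 28-nt window of the read's tag region (the first
#' `max_scan` nt) against the gene's reference 28-mers. A reference tag
#' matches a window if it has at most 1 Hamming mismatch within
#' positions 1-22 and at most 2 within positions 1-28. The unique
#' best-matching reference (fewest total mismatches) wins; a tie
#' between two distinct reference tags is ambiguous and returns no
#' match.
#'
#' @param read_sequence Character scalar: the read's tag region.
#' @param gene Gene id (no match if absent from the reference).
#' @param ref A [build_tag_reference()] object.
#' @param max_scan Scan only the first `max_scan` nt (default 200).
#' @return List with `tag` (matched reference 28-mer or `NA`),
#'   `observed` (the best window's sequence or `NA`), `mismatches`,
#'   and `status` in `"matched"`, `"ambiguous"`, `"unmatched"`,
#'   `"no_reference"`.
#' @export
match_ont_tag <- function(read_sequence, gene, ref, max_scan = 200L) {
  tags <- ref[[gene]]
  as.list(match_tags_batch(read_sequence, tags %||% character(0),
                           max_scan)[1L, ])
}

#' Detect an exact whitelist barcode in a read
#'
#' Strict path: returns a whitelist barcode present verbatim as a
#' 16-mer substring of the read's tag region; multiple distinct hits
#' are ambiguous and return `NA`.
#'
#' @param read_sequence Character scalar.
#' @param whitelist Character vector of 16-nt barcodes.
#' @param max_scan Scan only the first `max_scan` nt.
#' @return The barcode, or `NA` (attribute `status` gives
#'   `"matched"` / `"ambiguous"` / `"unmatched"`).
#' @export
exact_barcode_detect <- function(read_sequence, whitelist, max_scan = 200L) {
  stopifnot(length(whitelist) > 0L)
  region <- substr(read_sequence, 1L, max_scan)
  hits <- unique(whitelist[vapply(whitelist, function(b)
    grepl(b, region, fixed = TRUE), logical(1))])
  status <- if (length(hits) == 1L) "matched"
  else if (length(hits) > 1L) "ambiguous" else "unmatched"
  out <- if (length(hits) == 1L) hits else NA_character_
  structure(out, status = status)
}

#' Correct candidate molecules against the short-read reference
#'
#' Applies the molecule-inflation correction cascade to candidate
#' `(barcode, UMI, gene)` groups, processed per gene in descending
#' frequency order (ties broken lexicographically by tag). With `LevD`
#' the Levenshtein distance from the observed 28-mer to the nearest
#' reference tag of the same gene:
#'
#' * `LevD = 0`: kept as `illumina_confirmed`.
#' * `LevD` 1-2: the 28-mer is rewritten to the nearest reference tag
#'   and kept (`corrected`) if the corrected triplet is novel with
#'   respect to already-accepted molecules, else `merged`.
#' * `LevD > 3`, edit distance > 5 to every already-accepted tag of the
#'   gene: kept as `novel`.
#' * `LevD > 3`, edit distance 1-2 to an accepted tag: `merged` into
#'   that molecule.
#' * `LevD = 3` (`route_levd3 = TRUE` sends it down the `> 3` branch)
#'   and the `LevD > 3` / distance 3-5 gap (`route_mid_distance = TRUE`
#'   accepts as novel): `discarded` by default and counted, so that no
#'   molecule is silently invented.
#'
#' Edit distances to accepted molecules are computed on the full
#' 28-mer tag (barcode errors inflate molecules too).
#'
#' @param candidates Data frame with `gene_id`, `tag` (observed
#'   28-mer) and `count` (reads in the group).
#' @param ref A [build_tag_reference()].
#' @param route_levd3,route_mid_distance Route the two unspecified
#'   cascade cases instead of discarding.
#' @return Data frame of molecule records: `gene_id`, `barcode`, `umi`,
#'   `tag`, `tag_raw`, `status`, `levd`, `count`; attribute
#'   `case_counts` tallies every cascade branch.
#' @export
correct_umis <- function(candidates, ref, route_levd3 = FALSE,
                         route_mid_distance = FALSE) {
  stopifnot(all(c("gene_id", "tag", "count") %in% names(candidates)))
  tally <- c(illumina_confirmed = 0L, corrected = 0L, novel = 0L,
             merged = 0L, discarded_levd3 = 0L, discarded_mid = 0L,
             discarded_no_reference = 0L)
  res <- list()
  for (gid in unique(candidates$gene_id)) {
    cand <- candidates[candidates$gene_id == gid, , drop = FALSE]
    cand <- cand[order(-cand$count, cand$tag), , drop = FALSE]
    tags_ref <- ref[[gid]]
    has_ref <- !is.null(tags_ref) && length(tags_ref) > 0L
    dmat <- if (has_ref) utils::adist(cand$tag, tags_ref)
    accepted <- character(0)
    for (i in seq_len(nrow(cand))) {
      obs <- cand$tag[i]
      rec <- list(gene_id = gid, tag = obs, tag_raw = obs,
                  status = "discarded", levd = NA_integer_,
                  count = cand$count[i])
      if (!has_ref) {
        tally["discarded_no_reference"] <- tally["discarded_no_reference"] + 1L
        res[[length(res) + 1L]] <- rec
        next
      }
      d <- dmat[i, ]
      levd <- min(d)
      rec$levd <- as.integer(levd)
      branch_gt3 <- function(rec) {
        dmin <- if (length(accepted)) {
          da <- utils::adist(obs, accepted)[1L, ]
          min(da)
        } else Inf
        if (dmin > 5) {
          rec$status <- "novel"
        } else if (dmin <= 2) {
          rec$tag <- accepted[which.min(da)]
          rec$status <- "merged"
        } else if (route_mid_distance) {
          rec$status <- "novel"
        } else {
          rec$status <- "discarded"
          tally["discarded_mid"] <<- tally["discarded_mid"] + 1L
        }
        rec
      }
      if (levd == 0) {
        rec$status <- if (obs %in% accepted) "merged" else "illumina_confirmed"
      } else if (levd <= 2) {
        corr <- tags_ref[which.min(d)]
        rec$tag <- corr
        rec$status <- if (corr %in% accepted) "merged" else "corrected"
      } else if (levd == 3) {
        if (route_levd3) rec <- branch_gt3(rec)
        else { rec$status <- "discarded"
               tally["discarded_levd3"] <- tally["discarded_levd3"] + 1L }
      } else {
        rec <- branch_gt3(rec)
      }
      if (rec$status %in% c("illumina_confirmed", "corrected", "novel")) {
        accepted <- c(accepted, rec$tag)
        tally[rec$status] <- tally[rec$status] + 1L
      } else if (rec$status == "merged") {
        tally["merged"] <- tally["merged"] + 1L
      }
      res[[length(res) + 1L]] <- rec
    }
  }
  out <- if (length(res))
    do.call(rbind, lapply(res, function(r) data.frame(r, stringsAsFactors = FALSE)))
  else data.frame(gene_id = character(0), tag = character(0),
                  tag_raw = character(0), status = character(0),
                  levd = integer(0), count = integer(0))
  out$barcode <- substr(out$tag, 1L, 16L)
  out$umi <- substr(out$tag, 17L, 28L)
  out <- out[, c("gene_id", "barcode", "umi", "tag", "tag_raw", "status",
                 "levd", "count")]
  rownames(out) <- NULL
  structure(out, case_counts = tally)
}

#' Collapse reads to one molecule per (barcode, UMI, gene) triplet
#'
#' The representative read of each triplet is the one with the longest
#' aligned span; ties go to the lexicographically smallest read id.
#'
#' @param records Data frame with `read_id`, `barcode`, `umi`,
#'   `gene_id` and `span` (aligned span length).
#' @return One row per triplet, with `n_reads` support counts.
#' @export
deduplicate_molecules <- function(records) {
  stopifnot(all(c("read_id", "barcode", "umi", "gene_id", "span") %in%
                  names(records)))
  key <- paste(records$barcode, records$umi, records$gene_id, sep = "\r")
  ord <- order(key, -records$span, records$read_id)
  r <- records[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  out <- r[first, , drop = FALSE]
  out$n_reads <- as.integer(table(k)[k[first]])
  rownames(out) <- NULL
  out
}

#' Run the tag pipeline: match, correct, deduplicate
#'
#' Batched driver used by [run_pipeline()]: matches every read's tag
#' region to its gene's reference set, groups reads by observed 28-mer
#' and gene, runs the correction cascade, and deduplicates to one read
#' per molecule. Reads whose group was merged into an accepted
#' molecule keep that molecule's tag and collapse at deduplication.
#'
#' @param reads Read table (needs `read_id`, `gene_id`, `start`, `end`).
#' @param tags Data frame `read_id`, `tag_region`.
#' @param ref A [build_tag_reference()].
#' @param max_scan Tag-region scan length passed to the matcher.
#' @param ... Passed to [correct_umis()].
#' @return Deduplicated molecule-level read table with `barcode`,
#'   `umi`, `status` attached; attributes `n_unmatched`, `n_ambiguous`
#'   and `case_counts` report drop-out.
#' @export
process_tags <- function(reads, tags, ref, max_scan = 200L, ...) {
  stopifnot(inherits(ref, "tag_reference"))
  tagseq <- tags$tag_region[match(reads$read_id, tags$read_id)]
  obs <- rep(NA_character_, nrow(reads))
  status <- rep("no_reference", nrow(reads))
  for (gid in unique(reads$gene_id)) {
    idx <- which(reads$gene_id == gid)
    m <- match_tags_batch(tagseq[idx], ref[[gid]] %||% character(0), max_scan)
    obs[idx] <- m$observed
    status[idx] <- m$status
  }
  matched <- which(status == "matched")
  cand <- stats::aggregate(list(count = matched),
                           by = list(gene_id = reads$gene_id[matched],
                                     tag = obs[matched]),
                           FUN = length)
  corr <- correct_umis(cand, ref, ...)
  keepmask <- corr$status %in% c("illumina_confirmed", "corrected", "novel",
                                 "merged")
  tagmap <- stats::setNames(ifelse(keepmask, corr$tag, NA_character_),
                            paste(corr$gene_id, corr$tag_raw, sep = "\r"))
  final_tag <- unname(tagmap[paste(reads$gene_id[matched], obs[matched],
                                   sep = "\r")])
  keep <- !is.na(final_tag)
  out <- reads[matched[keep], , drop = FALSE]
  out$barcode <- substr(final_tag[keep], 1L, 16L)
  out$umi <- substr(final_tag[keep], 17L, 28L)
  out$span <- out$end - out$start
  dedup <- deduplicate_molecules(out)
  acc <- corr[corr$status %in% c("illumina_confirmed", "corrected", "novel"), ]
  stmap <- stats::setNames(acc$status, paste(acc$gene_id, acc$tag, sep = "\r"))
  dedup$status <- unname(stmap[paste(dedup$gene_id,
                                     paste0(dedup$barcode, dedup$umi),
                                     sep = "\r")])
  dedup$span <- NULL
  structure(dedup,
            n_unmatched = sum(status %in% c("unmatched", "no_reference")),
            n_ambiguous = sum(status == "ambiguous"),
            case_counts = attr(corr, "case_counts"))
}
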