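# In silico models of cDNA priming and fragmentation.

#' Priming-simulation configuration
#'
#' Defaults follow the printed protocol parameters: ten copies per
#' transcript, introns retained with probability 0.15, a 30-A tail,
#' 2-kb fragments, and poly(dT) priming at the longest A-rich stretch
#' with >= 8 As in a 10-bp window. `keep_side = "upstream"` keeps the
#' sequence 5' of the priming site (which makes poly(dT) capture
#' entire polyadenylated fragments); `"literal_right"` keeps the
#' sequence 3' of it.
#'
#' @param copies_per_transcript Copies simulated per transcript.
#' @param intron_retention_prob Per-intron retention probability.
#' @param polyA_append Number of As appended (default 30).
#' @param fragment_cut Fragment length in nt (default 2000).
#' @param polyT_min_a,polyT_window A-richness rule: at least
#'   `polyT_min_a` As in any `polyT_window`-bp window.
#' @param keep_side `"upstream"` or `"literal_right"`.
#' @param seed Integer seed.
#' @return A `priming_config` list.
#' @export
priming_config <- function(copies_per_transcript = 10L,
                           intron_retention_prob = 0.15,
                           polyA_append = 30L,
                           fragment_cut = 2000L,
                           polyT_min_a = 8L, polyT_window = 10L,
                           keep_side = c("upstream", "literal_right"),
                           seed = 1L) {
  keep_side <- match.arg(keep_side)
  stopifnot(intron_retention_prob >= 0, intron_retention_prob <= 1,
            copies_per_transcript >= 1L, fragment_cut > 0L)
  structure(list(copies_per_transcript = as.integer(copies_per_transcript),
                 intron_retention_prob = intron_retention_prob,
                 polyA_append = as.integer(polyA_append),
                 fragment_cut = as.integer(fragment_cut),
                 polyT_min_a = as.integer(polyT_min_a),
                 polyT_window = as.integer(polyT_window),
                 keep_side = keep_side, seed = as.integer(seed)),
            class = "priming_config")
}

# Longest A-rich stretch: positions covered by any window of
# `window` bp containing >= min_a As are merged into runs, and each
# run is trimmed to its first/last A (a qualifying window may overhang
# up to window - min_a non-A bases). Returns c(start, end) (1-based
# inclusive) of the longest trimmed run, ties to the 3'-most, or NULL
# when no window qualifies.
longest_a_rich <- function(seq, min_a = 8L, window = 10L) {
  x <- strsplit(seq, "", fixed = TRUE)[[1L]] == "A"
  n <- length(x)
  if (n < window) return(NULL)
  cs <- cumsum(c(0L, x))
  wa <- cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]
  qual <- which(wa >= min_a)
  if (!length(qual)) return(NULL)
  covered <- rep(FALSE, n)
  for (q in qual) covered[q:(q + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  bounds <- lapply(runs, function(k) {
    a_idx <- which(x[starts[k]:ends[k]]) + starts[k] - 1L
    c(min(a_idx), max(a_idx))
  })
  lens <- vapply(bounds, function(b) b[2L] - b[1L] + 1L, integer(1))
  best <- which(lens == max(lens))
  bounds[[best[length(best)]]]  # 3'-most on ties
}

#' Simulate poly(dT) or random-hexamer priming
#'
#' Each transcript copy retains introns at the configured probability
#' and gains a 30-A tail, is cut 5'-to-3' into fragments of
#' `fragment_cut` nt (plus a shorter terminal end), and each fragment
#' is classified `three_prime` (carries the tail) or `internal`.
#' Hexamer priming picks a uniform position; poly(dT) priming picks
#' the longest A-rich stretch (>= 8 As in a 10-bp window) and loses
#' fragments with no qualifying stretch. The configured side of the
#' priming site is kept as the captured molecule.
#'
#' @param transcripts List of transcript descriptions: each a list
#'   with `id`, `exons` (character vector of exon sequences) and
#'   optionally `introns` (length `length(exons) - 1`).
#' @param mode `"polyT"` or `"hexamer"`.
#' @param config A [priming_config()].
#' @return List with `fragments` (data frame: transcript, copy, kind,
#'   fragment length, captured length, covered_fraction) and
#'   `per_transcript` (captured fraction of total cDNA per
#'   transcript).
#' @export
simulate_priming <- function(transcripts, mode = c("polyT", "hexamer"),
                             config = priming_config()) {
  mode <- match.arg(mode)
  if (!length(transcripts)) stop("empty transcript set")
  with_seed(config$seed, {
    rows <- list()
    for (tr in transcripts) {
      nx <- length(tr$exons)
      introns <- tr$introns %||% character(0)
      for (cp in seq_len(config$copies_per_transcript)) {
        parts <- character(0)
        for (i in seq_len(nx)) {
          parts <- c(parts, tr$exons[i])
          if (i < nx && length(introns) >= i &&
              stats::runif(1L) < config$intron_retention_prob)
            parts <- c(parts, introns[i])
        }
        cdna <- paste0(paste0(parts, collapse = ""),
                       strrep("A", config$polyA_append))
        L <- nchar(cdna)
        body_len <- L - config$polyA_append
        cuts <- unique(c(seq(0L, L, by = config$fragment_cut), L))
        for (f in seq_len(length(cuts) - 1L)) {
          fs <- cuts[f] + 1L; fe <- cuts[f + 1L]
          frag <- substr(cdna, fs, fe)
          flen <- fe - fs + 1L
          kind <- if (fe == L) "three_prime" else "internal"
          # appended-tail bases falling inside this fragment (a cut
          # can split the tail across two fragments)
          tail_in <- max(0L, fe - max(fs - 1L, body_len))
          if (mode == "hexamer") {
            pos <- sample.int(flen, 1L)
            cap <- if (config$keep_side == "upstream") c(1L, pos)
            else c(pos, flen)
          } else {
            ar <- longest_a_rich(frag, config$polyT_min_a,
                                 config$polyT_window)
            cap <- if (is.null(ar)) NULL
            else if (config$keep_side == "upstream") {
              if (ar[1L] > 1L) c(1L, ar[1L] - 1L) else NULL
            } else {
              if (ar[2L] < flen) c(ar[2L] + 1L, flen) else NULL
            }
          }
          caplen <- if (is.null(cap)) 0L else cap[2L] - cap[1L] + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            transcript = tr$id, copy = cp, kind = kind, mode = mode,
            frag_start = fs - 1L, frag_end = fe, frag_len = flen,
            cap_start = if (is.null(cap)) NA_integer_ else fs - 1L + cap[1L] - 1L,
            cap_end = if (is.null(cap)) NA_integer_ else fs - 1L + cap[2L],
            captured = caplen,
            covered_fraction = caplen / flen,
            tail_len = tail_in,
            stringsAsFactors = FALSE)
        }
      }
    }
    fragments <- do.call(rbind, rows)
    per_tx <- do.call(rbind, lapply(split(fragments, fragments$transcript),
                                    function(d) data.frame(
                                      transcript = d$transcript[1L],
                                      covered_fraction = sum(d$captured) /
                                        sum(d$frag_len),
                                      mean_fragment_len = mean(d$frag_len),
                                      stringsAsFactors = FALSE)))
    rownames(per_tx) <- NULL
    list(fragments = fragments, per_transcript = per_tx)
  })
}

#' Simulate cDNA fragmentation into short-read tags
#'
#' Per read, a random number of 3' nucleotides remains (normal, mean
#' 250, sd 50 by default; non-positive draws rejected, then clipped to
#' `[tag_len, read length]`), and the 5'-most `tag_len` nt of that
#' remainder become the short-read tag. Reads shorter than `tag_len`
#' are used whole (counted).
#'
#' @param read_lengths Integer vector of read lengths (nt).
#' @param mean,sd Normal parameters of the remaining-3'-length draw.
#' @param tag_len Tag length (default 76).
#' @param seed Integer seed.
#' @return Data frame `length`, `kept`, `tag_start`, `tag_end`
#'   (0-based half-open read coordinates); attribute `n_short` counts
#'   too-short reads.
#' @export
simulate_fragmentation <- function(read_lengths, mean = 250, sd = 50,
                                   tag_len = 76L, seed = 1L) {
  with_seed(seed, {
    n <- length(read_lengths)
    k <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- stats::rnorm(1L, mean, sd)
        if (v > 0) break
      }
      k[i] <- v
    }
    k <- pmin(pmax(round(k), tag_len), read_lengths)
    short <- read_lengths < tag_len
    k[short] <- read_lengths[short]
    tag_start <- read_lengths - k
    tag_end <- pmin(tag_start + tag_len, read_lengths)
    structure(data.frame(length = read_lengths, kept = k,
                         tag_start = tag_start, tag_end = tag_end),
              n_short = sum(short))
  })
}

#' Normalized 5'-to-3' coverage profile
#'
#' Splits each transcript into `bins` equal spans 5' to 3', computes
#' per-bin per-base coverage from the mapped features, divides by the
#' transcript's mean coverage, and averages over transcripts
#' (zero-coverage transcripts skipped, counted).
#'
#' @param features Data frame `transcript`, `start`, `end` in 0-based
#'   half-open transcript coordinates.
#' @param tx_lengths Named integer vector of transcript lengths.
#' @param bins Number of bins (default 100).
#' @return Numeric vector of length `bins` (attribute `n_skipped`).
#' @export
coverage_profile <- function(features, tx_lengths, bins = 100L) {
  prof <- matrix(NA_real_, nrow = length(tx_lengths), ncol = bins)
  skipped <- 0L
  for (t in seq_along(tx_lengths)) {
    id <- names(tx_lengths)[t]
    L <- tx_lengths[[t]]
    f <- features[features$transcript == id, , drop = FALSE]
    if (!nrow(f)) { skipped <- skipped + 1L; next }
    cov <- numeric(L)
    for (i in seq_len(nrow(f))) {
      s <- max(0L, f$start[i]); e <- min(L, f$end[i])
      if (e > s) cov[(s + 1L):e] <- cov[(s + 1L):e] + 1
    }
    if (sum(cov) == 0) { skipped <- skipped + 1L; next }
    edges <- round(seq(0L, L, length.out = bins + 1L))
    bc <- vapply(seq_len(bins), function(b) {
      if (edges[b + 1L] == edges[b]) return(0)
      mean(cov[(edges[b] + 1L):edges[b + 1L]])
    }, numeric(1))
    prof[t, ] <- bc / mean(cov)
  }
  out <- colMeans(prof, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  structure(out, n_skipped = skipped)
}
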