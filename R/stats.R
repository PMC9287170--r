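#' Odds ratio and log-odds for a 2x2 inclusion table
#'
#' Computes `[(in-in) * (out-out)] / [(in-out) * (out-in)]` after
#' replacing zero cells by 0.5 (Haldane-Anscombe style continuity), and
#' its logarithm in a configurable base. The base defaults to 2 so that
#' an absolute log-odds of 7 corresponds to a 128-fold enrichment of the
#' concordant over the discordant exon combinations.
#'
#' @param counts Numeric vector of length 4: `in_in`, `in_out`,
#'   `out_in`, `out_out` (or a 2x2 matrix in that layout, row-major).
#' @param base Logarithm base for the log-odds (default 2).
#' @return A list with `odds_ratio` and `log_odds`.
#' @examples
#' odds_ratio(c(20, 5, 5, 20))   # OR = 16, log2 = 4
#' odds_ratio(c(10, 0, 0, 10))   # zeros -> 0.5, OR = 400
#' @export
odds_ratio <- function(counts, base = 2) {
  if (is.matrix(counts)) counts <- as.vector(t(counts))
  stopifnot(length(counts) == 4L, all(counts >= 0))
  x <- ifelse(counts == 0, 0.5, counts)
  or <- (x[1L] * x[4L]) / (x[2L] * x[3L])
  list(odds_ratio = or, log_odds = log(or, base = base))
}

#' Fold enrichment implied by an absolute log-odds ratio
#'
#' @param lor Log-odds ratio (any sign).
#' @param base Logarithm base the log-odds was taken in (default 2).
#' @return `base^abs(lor)`.
#' @examples
#' lor_to_fold(7)  # 128
#' @export
lor_to_fold <- function(lor, base = 2) base^abs(lor)

#' Expected-count matrix under independence
#'
#' `E[i, j] = rowsum_i * colsum_j / total`, preserving both margins.
#'
#' @param M Non-negative count matrix.
#' @return Matrix of expected counts, same shape as `M`.
#' @export
expected_matrix <- function(M) {
  M <- as.matrix(M)
  tot <- sum(M)
  if (tot == 0) return(matrix(0, nrow(M), ncol(M)))
  outer(rowSums(M), colSums(M)) / tot
}

#' Pearson chi-squared test of association
#'
#' Plain Pearson statistic `sum((M - E)^2 / E)` on an r x c count
#' matrix with `df = (r - 1)(c - 1)`, optionally with the Yates
#' continuity correction on 2x2 tables. Rows or columns whose sum is
#' zero are dropped before testing.
#'
#' @param M Non-negative count matrix.
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(M, correct = FALSE) {
  M <- as.matrix(M)
  M <- M[rowSums(M) > 0, , drop = FALSE]
  M <- M[, colSums(M) > 0, drop = FALSE]
  if (nrow(M) < 2L || ncol(M) < 2L) {
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, expected = expected_matrix(M)))
  }
  E <- expected_matrix(M)
  dev <- abs(M - E)
  if (correct && nrow(M) == 2L && ncol(M) == 2L) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  df <- (nrow(M) - 1L) * (ncol(M) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = E)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up FDR control valid under arbitrary dependence, inflating the
#' Benjamini-Hochberg threshold by the harmonic sum `c(m) = sum(1/i)`.
#' `NA` p-values are passed through unadjusted.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted values, elementwise at least the BH adjustment.
#' @export
adjust_fdr_by <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BY")
}

#' Joint cell probabilities of a bivariate Bernoulli
#'
#' Solves, in closed form, for the 2x2 cell probabilities of a pair of
#' Bernoulli variables with given marginal success probabilities and a
#' given odds ratio (the Plackett construction). An odds ratio of 1
#' gives independence. Triples that admit no valid joint distribution
#' are rejected with an error, never clipped.
#'
#' @param p1,p2 Marginal inclusion probabilities in `[0, 1]`.
#' @param or Target odds ratio, `> 0`.
#' @return Named numeric vector `c(p11, p10, p01, p00)` summing to 1.
#' @examples
#' biv_bernoulli_probs(0.5, 0.5, 16)
#' @export
biv_bernoulli_probs <- function(p1, p2, or) {
  stopifnot(length(p1) == 1L, length(p2) == 1L, length(or) == 1L)
  if (is.na(p1) || is.na(p2) || is.na(or) ||
      p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1 || or <= 0)
    stop("need marginals in [0,1] and odds ratio > 0")
  degenerate <- p1 %in% c(0, 1) || p2 %in% c(0, 1)
  if (degenerate && or != 1)
    stop(sprintf("infeasible (psi1=%g, psi2=%g, OR=%g): %s",
                 p1, p2, or,
                 "a degenerate marginal admits no odds ratio other than 1"))
  if (or == 1) {
    p11 <- p1 * p2
  } else {
    s <- 1 + (p1 + p2) * (or - 1)
    disc <- s^2 - 4 * or * (or - 1) * p1 * p2
    p11 <- (s - sqrt(disc)) / (2 * (or - 1))
  }
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop(sprintf("infeasible (psi1=%g, psi2=%g, OR=%g)", p1, p2, or))
  p11 <- min(max(p11, lo), hi)
  out <- c(p11 = p11, p10 = p1 - p11, p01 = p2 - p11, p00 = 1 - p1 - p2 + p11)
  if (any(out < -1e-12))
    stop(sprintf("infeasible (psi1=%g, psi2=%g, OR=%g)", p1, p2, or))
  pmax(out, 0)
}

# Draw n correlated inclusion-indicator pairs. Returns a 2-column 0/1 matrix.
draw_biv_bernoulli <- function(n, p1, p2, or) {
  pr <- biv_bernoulli_probs(p1, p2, or)
  cell <- sample.int(4L, n, replace = TRUE, prob = pr)
  cbind(first = as.integer(cell %in% c(1L, 2L)),
        second = as.integer(cell %in% c(1L, 3L)))
}
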