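#' The chi-squared testability criterion
#'
#' Classifies a contingency table of RNA-variable counts as `testable`,
#' `constitutive` or `low_counts` from its expected-count matrix under
#' independence. The rules are applied in this fixed order:
#'
#' 1. **testable** -- at least 80% of cells (rounded to the nearest
#'    integer; round-half-to-even) have expected count >= 5 *and* every
#'    cell has expected count >= 1. The p-value may then be computed.
#' 2. **constitutive** -- otherwise, if the median expected count is
#'    < 5 in any row or any column, the RNA variable (TSS, exon or
#'    polyA site) indexed by that row/column is effectively fixed in
#'    this context.
#' 3. **low_counts** -- otherwise.
#'
#' An all-zero matrix is `low_counts`. Note the fixed rule order means a
#' balanced-but-shallow table whose row/column median expected counts
#' are all exactly 5 falls through to `low_counts` even though no
#' variable is fixed; the per-class audit fields let callers inspect
#' this.
#'
#' @param M Non-negative count matrix (rows = one variable's levels,
#'   columns = the other's; for exon pairs a 2x2, for end-site matrices
#'   n x 2).
#' @return A list with `class` (one of `"testable"`, `"constitutive"`,
#'   `"low_counts"`), `expected` (the expected matrix), and
#'   `constitutive_rows` / `constitutive_cols` (integer indices of
#'   offending rows/columns, empty unless `class == "constitutive"`).
#' @examples
#' chi2_criterion(matrix(10, 2, 2))  # testable
#' @export
chi2_criterion <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0) || any(is.na(M))) stop("counts must be non-negative")
  E <- expected_matrix(M)
  res <- list(class = "low_counts", expected = E,
              constitutive_rows = integer(0), constitutive_cols = integer(0))
  if (sum(M) == 0) return(res)
  need <- round(0.8 * length(E))
  if (sum(E >= 5) >= need && all(E >= 1)) {
    res$class <- "testable"
    return(res)
  }
  bad_rows <- which(apply(E, 1L, stats::median) < 5)
  bad_cols <- which(apply(E, 2L, stats::median) < 5)
  if (length(bad_rows) || length(bad_cols)) {
    res$class <- "constitutive"
    res$constitutive_rows <- bad_rows
    res$constitutive_cols <- bad_cols
  }
  res
}
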