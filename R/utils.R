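# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that no exported operation leaks
#' randomness into, or depends on, the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  force(seed)  # the seed expression may itself consume RNG draws
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read / write the package's TSV dialect
#'
#' Tab-separated, header row, `"NA"` as the missing token, UTF-8, LF
#' line endings, no quoting.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns
#'   `path` invisibly.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = NA,
                    fileEncoding = "UTF-8")
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

DNA <- c("A", "C", "G", "T")

# n random DNA strings of length len (uses current RNG state)
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# n distinct random DNA strings of length len
random_dna_unique <- function(n, len) {
  out <- unique(random_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), len)))
  }
  out[seq_len(n)]
}

is_dna <- function(x) !is.na(x) & grepl("^[ACGT]+$", x)

# One-hot encode equal-length DNA strings as a (4*len) x n 0/1 matrix.
# Used for batched Hamming comparisons via crossprod.
dna_onehot <- function(strings, len) {
  n <- length(strings)
  out <- matrix(0L, nrow = 4L * len, ncol = n)
  if (n == 0L) return(out)
  ints <- vapply(strings, utf8ToInt, integer(len), USE.NAMES = FALSE)
  if (is.null(dim(ints))) ints <- matrix(ints, nrow = len)
  code <- match(ints, utf8ToInt("ACGT"))  # len x n, NA for non-ACGT
  pos <- rep(seq_len(len), times = n)
  col <- rep(seq_len(n), each = len)
  keep <- !is.na(code)
  out[cbind((pos[keep] - 1L) * 4L + code[keep], col[keep])] <- 1L
  out
}

#' Serialize and parse exon-block strings
#'
#' Blocks are stored in the read table as `"start-end,start-end"` with
#' 0-based half-open coordinates, sorted and non-overlapping.
#'
#' @param blocks A 2-column matrix (start, end) or list of such matrices.
#' @param x Character vector of encoded block strings.
#' @return `format_blocks()` a character vector; `parse_blocks()` a list
#'   of 2-column integer matrices.
#' @export
format_blocks <- function(blocks) {
  if (is.matrix(blocks)) blocks <- list(blocks)
  vapply(blocks, function(b) {
    paste(paste0(b[, 1L], "-", b[, 2L]), collapse = ",")
  }, character(1))
}

#' @rdname format_blocks
#' @export
parse_blocks <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(parts) {
    se <- strsplit(parts, "-", fixed = TRUE)
    m <- matrix(as.integer(unlist(se)), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
    if (any(is.na(m)) || any(m[, 2L] <= m[, 1L]))
      stop("malformed block string: ", x[1L])
    m
  })
}

# Validate a block matrix: sorted, non-overlapping, end > start.
valid_blocks <- function(b) {
  is.matrix(b) && ncol(b) == 2L && all(b[, 2L] > b[, 1L]) &&
    (nrow(b) < 2L || all(diff(b[, 1L]) > 0 & b[-nrow(b), 2L] <= b[-1L, 1L]))
}
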