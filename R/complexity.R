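#' Lempel-Ziv (LZ76) complexity of a binary sequence
#'
#' Counts the phrases of the exhaustive-history LZ76 parsing: each new
#' phrase is the shortest prefix of the remainder that cannot be reproduced
#' by copying from the text already seen (self-referential copies allowed);
#' a terminal phrase that is still reproducible when the sequence ends
#' counts as one phrase.  No terminal-phrase adjustment is applied.
#'
#' @param bits Binary sequence: an integer/numeric vector of 0s and 1s, a
#'   logical vector, a `binary_code`, or a character string like `"0101"`.
#' @return Integer phrase count (`1 <= c <= n`).
#' @export
#'
#' @examples
#' lz76("0000000000")  # 2: parses as 0 | 000000000
#' lz76("0101010101")  # 3
lz76 <- function(bits) {
  b <- as_bits(bits)
  if (length(b) == 0L) ps_stop("sequence must be non-empty", "lz_invalid")
  lz76_phrases_cpp(b)
}

#' Normalized LZ76 complexity
#'
#' `c * log2(n) / n`, where `c` is the LZ76 phrase count and `n` the
#' sequence length.  Approaches 1 for long i.i.d. fair-coin sequences.
#'
#' @inheritParams lz76
#' @return Normalized complexity (dimensionless, > 0).
#' @export
lz_normalized <- function(bits) {
  b <- as_bits(bits)
  n <- length(b)
  if (n < 2L) ps_stop("need a sequence of length >= 2", "lz_invalid")
  lz76_phrases_cpp(b) * log2(n) / n
}

#' Binarize a weight matrix into a bit sequence
#'
#' Row-major scan of the matrix; bit = 1 iff the entry is strictly
#' positive.  Bridges weight maps to the complexity measure.
#'
#' @param w A `weight_matrix` (from [init_weights]) or a plain matrix.
#' @return Integer 0/1 vector of length `n^2`.
#' @export
#'
#' @examples
#' binarize_matrix(matrix(c(0.5, -0.1, -0.2, 0.9), 2, 2))  # 1 0 0 1
binarize_matrix <- function(w) {
  W <- if (inherits(w, "weight_matrix")) w$W else w
  if (!is.matrix(W)) ps_stop("w must be a matrix", "lz_invalid")
  as.integer(t(W) > 0)  # transpose: row-major order
}

# coerce the accepted representations to an integer 0/1 vector
as_bits <- function(bits) {
  if (inherits(bits, "binary_code")) return(bits$bits)
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L)
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  if (is.logical(bits)) bits <- as.integer(bits)
  if (!is.numeric(bits) || anyNA(bits) || !all(bits %in% c(0, 1)))
    ps_stop("sequence must contain only 0s and 1s", "lz_nonbinary")
  as.integer(bits)
}
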