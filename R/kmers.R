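#' Enumerate all DNA k-mers
#'
#' There are `4^k` DNA words of length `k`; for `k = 8` that is the 65,536
#' 8-mers probed on a protein binding microarray.
#'
#' @param k Word length, a positive integer. Materialized enumeration is
#'   limited to `k <= 12` (16.7 million words).
#' @param materialize If `TRUE` (default) return the character vector of all
#'   k-mers in lexicographic order; if `FALSE` return only the count.
#' @return A character vector of length `4^k`, or the count as a number when
#'   `materialize = FALSE`.
#' @examples
#' enumerate_kmers(8, materialize = FALSE)
#' head(enumerate_kmers(2))
#' @export
enumerate_kmers <- function(k, materialize = TRUE) {
  check_number(k, "k", min = 1, integerish = TRUE)
  if (!materialize) {
    return(4^k)
  }
  if (k > 12) {
    eq_abort("materialized enumeration supports k <= 12; use materialize = FALSE.",
             "eq_config_error")
  }
  digits <- kmer_digit_matrix(k)
  kmers_from_digits(digits)
}

#' @rdname enumerate_kmers
#' @export
kmer_count <- function(k) {
  enumerate_kmers(k, materialize = FALSE)
}

# matrix of base-4 digits (0 = A ... 3 = T), one row per k-mer in
# lexicographic order
kmer_digit_matrix <- function(k) {
  n <- 4^k
  idx <- seq_len(n) - 1
  digits <- matrix(0L, nrow = n, ncol = k)
  for (p in seq_len(k)) {
    digits[, p] <- (idx %/% 4^(k - p)) %% 4
  }
  digits
}

kmers_from_digits <- function(digits) {
  cols <- lapply(seq_len(ncol(digits)), function(p) DNA_BASES[digits[, p] + 1])
  do.call(paste0, cols)
}

kmer_to_digits <- function(kmer) {
  match(strsplit(kmer, "")[[1]], DNA_BASES) - 1L
}

# index (0-based) of the reverse complement of every row of a digit matrix
rc_index <- function(digits) {
  k <- ncol(digits)
  idx <- numeric(nrow(digits))
  for (p in seq_len(k)) {
    idx <- idx + (3 - digits[, k + 1 - p]) * 4^(k - p)
  }
  idx
}
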