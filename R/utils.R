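DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the `A,C,G,T,N` alphabet.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Integer codes 1..4 for A,C,G,T; NA for N (and anything else).
seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    stop(sprintf("'%s' must be a single finite number in %s%g, %g%s, got: %s",
                 name, if (closed_lower) "[" else "(", lower, upper,
                 if (closed_upper) "]" else ")",
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# All length-m words over ACGT in lexicographic order ("" for m = 0).
# Index of context (c1..cm) is 1 + sum((code_j - 1) * 4^(m - j)).
all_contexts <- function(m) {
  if (m == 0L) return("")
  idx <- 0:(4L^m - 1L)
  chars <- vapply(seq_len(m), function(j) {
    DNA_BASES[(idx %/% 4L^(m - j)) %% 4L + 1L]
  }, character(length(idx)))
  if (m == 1L) return(as.character(chars))
  apply(chars, 1L, paste, collapse = "")
}

# Map integer base codes of an m-length context window to its context index.
codes_to_context_idx <- function(codes_mat, m) {
  # codes_mat: matrix with m columns of codes 1..4 (rows = windows)
  idx <- rep(0L, nrow(codes_mat))
  for (j in seq_len(m)) idx <- idx + (codes_mat[, j] - 1L) * 4L^(m - j)
  idx + 1L
}
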