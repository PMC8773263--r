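#' Position frequency matrix
#'
#' A PFM stores, for one transcription-factor motif, the probability of each
#' base at each motif position. Rows are positions, columns are `A,C,G,T` and
#' each row sums to 1.
#'
#' @param probs Numeric matrix (w x 4) of per-position base probabilities.
#'   Rows are renormalised when their sum is within `1e-3` of 1; anything
#'   further off is an error.
#' @param tf_id Transcription factor identifier.
#' @param motif_id Motif identifier (one TF may own several motifs).
#' @return An object of class `pfm`.
#' @examples
#' pfm(matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE), "TF1", "M1")
#' @export
pfm <- function(probs, tf_id, motif_id = tf_id) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L) stop("a PFM needs at least one position", call. = FALSE)
  if (ncol(probs) != 4L) stop("a PFM needs exactly 4 columns (A,C,G,T)", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("PFM probabilities must be finite and non-negative", call. = FALSE)
  }
  sums <- rowSums(probs)
  bad <- which(abs(sums - 1) > 1e-3)
  if (length(bad)) {
    stop(sprintf("PFM row %d sums to %.6g, outside [1 - 1e-3, 1 + 1e-3]",
                 bad[1], sums[bad[1]]), call. = FALSE)
  }
  probs <- probs / sums
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(tf_id = as.character(tf_id),
                 motif_id = as.character(motif_id),
                 probs = probs),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s / %s, width %d, consensus %s\n",
              x$tf_id, x$motif_id, nrow(x$probs), pfm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PFM
#'
#' @param x A [pfm] object.
#' @return Single string: the most probable base at each position (ties go to
#'   the alphabetically first base).
#' @export
pfm_consensus <- function(x) {
  stopifnot(inherits(x, "pfm"))
  paste(DNA_BASES[apply(x$probs, 1L, which.max)], collapse = "")
}

pfm_width <- function(x) nrow(x$probs)
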