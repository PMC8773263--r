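#' Estimate an order-m Markov background model from sequences
#'
#' Builds the null model used for motif scoring and binding-site p-values:
#' each base's probability is conditioned on the preceding `m` bases.
#' Counts are pooled over the sequences and (by default) their reverse
#' complements, so the background is strand-symmetric. Windows containing
#' `N` are skipped.
#'
#' @param sequences Named character vector of nucleotide sequences
#'   (a `SequenceSet`, e.g. from [read_fasta()]).
#' @param m Markov order (non-negative integer; the pipeline default is 2).
#' @param pseudo_count Pseudo-count added to every (context, base) cell so all
#'   transition probabilities are strictly positive. Default 1.
#' @param pool_strands Pool counts with the reverse-complement strand
#'   (default `TRUE`).
#' @return An object of class `markov_bg` with elements `order`,
#'   `transition` (4^m x 4 matrix, rows = contexts), `context_probs`
#'   (smoothed marginal context frequencies, used to initialise the score
#'   distribution dynamic programme) and `stationary` (marginal base
#'   frequencies).
#' @export
build_markov_background <- function(sequences, m, pseudo_count = 1,
                                    pool_strands = TRUE) {
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m != round(m)) {
    stop("Markov order 'm' must be a non-negative integer", call. = FALSE)
  }
  m <- as.integer(m)
  assert_scalar_number(pseudo_count, "pseudo_count", lower = 0)
  sequences <- as.character(sequences)
  if (sum(nchar(sequences)) == 0L) {
    stop("total sequence length must be positive", call. = FALSE)
  }
  pool <- sequences
  if (pool_strands) pool <- c(pool, revcomp(sequences))

  base_counts <- stats::setNames(numeric(4), DNA_BASES)
  contexts <- all_contexts(m)
  K <- length(contexts)
  trans_counts <- matrix(0, nrow = K, ncol = 4L,
                         dimnames = list(contexts, DNA_BASES))

  for (seq in pool) {
    codes <- seq_to_codes(seq)
    tab <- tabulate(codes, nbins = 4L)
    base_counts <- base_counts + tab
    n <- length(codes)
    if (n < m + 1L) next
    if (m == 0L) {
      trans_counts[1L, ] <- trans_counts[1L, ] + tab
    } else {
      # windows of length m+1; drop any containing N
      win <- stats::embed(codes, m + 1L)[, (m + 1L):1L, drop = FALSE]
      ok <- stats::complete.cases(win)
      if (!any(ok)) next
      win <- win[ok, , drop = FALSE]
      ctx <- codes_to_context_idx(win[, seq_len(m), drop = FALSE], m)
      nxt <- win[, m + 1L]
      inc <- table(factor(ctx, levels = seq_len(K)), factor(nxt, levels = 1:4))
      trans_counts <- trans_counts + as.matrix(inc)
    }
  }

  ctx_tot <- rowSums(trans_counts)
  transition <- (trans_counts + pseudo_count) / (ctx_tot + 4 * pseudo_count)
  context_probs <- (ctx_tot + pseudo_count) / (sum(ctx_tot) + K * pseudo_count)
  names(context_probs) <- contexts
  stationary <- (base_counts + pseudo_count) / (sum(base_counts) + 4 * pseudo_count)

  structure(list(order = m,
                 transition = transition,
                 context_probs = context_probs,
                 stationary = stationary,
                 pseudo_count = pseudo_count,
                 pool_strands = pool_strands),
            class = "markov_bg")
}

#' @export
print.markov_bg <- function(x, ...) {
  cat(sprintf("<markov_bg> order %d, stationary A/C/G/T = %s\n", x$order,
              paste(sprintf("%.3f", x$stationary), collapse = "/")))
  invisible(x)
}
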