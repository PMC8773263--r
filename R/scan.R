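#' Convert a PFM to a log-ratio weight matrix
#'
#' Each motif frequency is smoothed with a pseudo-frequency,
#' `f'(i,b) = (f(i,b) + pf) / (1 + 4 pf)`, and scored against the
#' background's stationary base distribution:
#' `weight(i,b) = ln f'(i,b) - ln stationary(b)`. The order-m Markov context
#' enters at the p-value stage, where the chain governs letter generation
#' (see [score_pvalue_table()]).
#'
#' @param pfm A [pfm] object.
#' @param background A `markov_bg` from [build_markov_background()].
#' @param pseudo_frequency Positive smoothing constant (default 0.001).
#' @return An object of class `pwm_weights` with a `w x 4` matrix of finite
#'   natural-log weights.
#' @export
pfm_to_weight_matrix <- function(pfm, background, pseudo_frequency = 0.001) {
  stopifnot(inherits(pfm, "pfm"), inherits(background, "markov_bg"))
  assert_scalar_number(pseudo_frequency, "pseudo_frequency", lower = 0,
                       closed_lower = FALSE)
  corrected <- (pfm$probs + pseudo_frequency) / (1 + 4 * pseudo_frequency)
  weights <- sweep(log(corrected), 2L, log(background$stationary), `-`)
  structure(list(tf_id = pfm$tf_id, motif_id = pfm$motif_id,
                 weights = weights, pseudo_frequency = pseudo_frequency),
            class = "pwm_weights")
}

#' Exact score distribution and p-values under the Markov background
#'
#' Weights are discretised by rounding *down* to multiples of `granularity`
#' (in natural-log units), then the exact distribution of the total window
#' score under the background is computed by dynamic programming over
#' (position, Markov context, discretised score). Letters are generated by
#' the order-m chain (initial context drawn from the smoothed context
#' frequencies); scores use the same stationary-background weights as the
#' scanner, so scan scores and p-values are mutually consistent.
#' `pvalue(s) = P(score >= s)` is non-increasing, equals 1 at the minimum
#' achievable score, and rounding down makes reported p-values conservative
#' (inflated by at most `w * granularity` in score units).
#'
#' @param wm A `pwm_weights` from [pfm_to_weight_matrix()].
#' @param background The `markov_bg` the weights were built against.
#' @param granularity Positive score bin width (default 1e-3).
#' @return An object of class `score_dist` with the discretised weight bins
#'   (`wbin`), the score `support`, point probabilities `prob` and the tail
#'   probabilities `pvalue`.
#' @export
score_pvalue_table <- function(wm, background, granularity = 1e-3) {
  stopifnot(inherits(wm, "pwm_weights"), inherits(background, "markov_bg"))
  assert_scalar_number(granularity, "granularity", lower = 0, closed_lower = FALSE)
  w <- nrow(wm$weights)
  m <- background$order
  wbin <- matrix(as.integer(floor(wm$weights / granularity)), nrow = w)
  row_min <- apply(wbin, 1L, min)
  row_max <- apply(wbin, 1L, max)
  minsum <- sum(row_min)
  maxsum <- sum(row_max)

  K <- 4L^m
  trans <- background$transition
  # context index after emitting base b from context c (suffix of length m)
  if (m > 0L) {
    next_ctx <- matrix(0L, nrow = K, ncol = 4L)
    for (c in seq_len(K)) {
      suffix <- (c - 1L) %% 4L^(m - 1L)
      next_ctx[c, ] <- suffix * 4L + 0:3 + 1L
    }
  } else {
    next_ctx <- matrix(1L, nrow = 1L, ncol = 4L)
  }

  P <- matrix(background$context_probs, nrow = K, ncol = 1L)
  run_min <- 0L
  for (i in seq_len(w)) {
    span <- row_max[i] - row_min[i]
    Lold <- ncol(P)
    Pnew <- matrix(0, nrow = K, ncol = Lold + span)
    for (c in seq_len(K)) {
      if (all(P[c, ] == 0)) next
      for (b in 1:4) {
        tp <- trans[c, b]
        if (is.na(tp) || tp == 0) next
        off <- wbin[i, b] - row_min[i]
        cols <- seq_len(Lold) + off
        cc <- next_ctx[c, b]
        Pnew[cc, cols] <- Pnew[cc, cols] + P[c, ] * tp
      }
    }
    P <- Pnew
    run_min <- run_min + row_min[i]
  }
  prob <- colSums(P)
  # guard tiny negative / drifted mass
  prob[prob < 0] <- 0
  pvalue <- rev(cumsum(rev(prob)))
  pvalue <- pmin(pvalue, 1)
  support <- (minsum:maxsum) * granularity
  structure(list(tf_id = wm$tf_id, motif_id = wm$motif_id,
                 granularity = granularity, wbin = wbin,
                 minsum = minsum, maxsum = maxsum,
                 support = support, prob = prob, pvalue = pvalue),
            class = "score_dist")
}

# p-value for integer bin sums (vectorised); bin sums always lie in
# [minsum, maxsum] when computed with dist$wbin.
lookup_pvalue <- function(dist, binsum) {
  idx <- pmin(pmax(binsum - dist$minsum + 1L, 1L), length(dist$pvalue))
  dist$pvalue[idx]
}

scan_one_strand <- function(codes, wm, dist) {
  w <- nrow(wm$weights)
  n <- length(codes) - w + 1L
  if (n < 1L) return(NULL)
  score <- numeric(n)
  binsum <- integer(n)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n - 1L)]
    score <- score + wm$weights[i, ci]
    binsum <- binsum + dist$wbin[i, ci]
  }
  list(score = score, binsum = binsum, n = n)
}

#' Scan one sequence for binding sites
#'
#' Every window of width w on the requested strand(s) is scored as the sum of
#' per-position weights; windows containing `N` are skipped; a hit is
#' reported iff its p-value is at or below `p_threshold`. Positions are
#' always reported on the forward coordinate system; minus-strand windows are
#' scored on the reverse complement and `matched_word` is the motif-oriented
#' word.
#'
#' @param seq A single nucleotide string.
#' @param wm A `pwm_weights`.
#' @param background The matching `markov_bg` (kept for interface symmetry;
#'   scores use the stationary weights baked into `wm`).
#' @param dist The matching `score_dist`.
#' @param p_threshold Site-calling p-value threshold (default 1e-5).
#' @param strands `"both"` (default) or `"forward"`.
#' @param gene_id Optional id copied into the hit table.
#' @return `data.frame` with columns `tf_id`, `motif_id`, `gene_id`, `start`,
#'   `strand`, `matched_word`, `score`, `pvalue`.
#' @export
scan_sequence <- function(seq, wm, background, dist, p_threshold = 1e-5,
                          strands = c("both", "forward"),
                          gene_id = NA_character_) {
  stopifnot(inherits(wm, "pwm_weights"), inherits(dist, "score_dist"))
  strands <- match.arg(strands)
  assert_scalar_number(p_threshold, "p_threshold", lower = 0, upper = 1,
                       closed_lower = FALSE)
  empty <- data.frame(tf_id = character(0), motif_id = character(0),
                      gene_id = character(0), start = integer(0),
                      strand = character(0), matched_word = character(0),
                      score = numeric(0), pvalue = numeric(0))
  seq <- toupper(seq)
  L <- nchar(seq)
  w <- nrow(wm$weights)
  if (L < w) return(empty)

  collect <- function(seq_str, minus) {
    codes <- match(strsplit(seq_str, "", fixed = TRUE)[[1]], DNA_BASES)
    sc <- scan_one_strand(codes, wm, dist)
    if (is.null(sc)) return(NULL)
    ok <- !is.na(sc$score)
    if (!any(ok)) return(NULL)
    pv <- rep(NA_real_, sc$n)
    pv[ok] <- lookup_pvalue(dist, sc$binsum[ok])
    hit <- which(ok & pv <= p_threshold)
    if (!length(hit)) return(NULL)
    start_fwd <- if (minus) L - hit - w + 2L else hit
    data.frame(tf_id = wm$tf_id, motif_id = wm$motif_id, gene_id = gene_id,
               start = start_fwd, strand = if (minus) "-" else "+",
               matched_word = substring(seq_str, hit, hit + w - 1L),
               score = sc$score[hit], pvalue = pv[hit])
  }

  res <- list(collect(seq, minus = FALSE))
  if (strands == "both") res <- c(res, list(collect(revcomp(seq), minus = TRUE)))
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a promoter set with a collection of PFMs
#'
#' The Markov background is estimated once from the promoter set itself
#' (strand-pooled), each PFM is converted to a weight matrix, its exact score
#' distribution is computed, and every promoter is scanned on both strands.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param pfms List of [pfm] objects.
#' @param m Markov background order (default 2).
#' @param p_threshold Site-calling p-value threshold (default 1e-5).
#' @param pseudo_frequency PFM smoothing constant (default 0.001).
#' @param granularity Score discretisation (default 1e-3).
#' @param strands `"both"` or `"forward"`.
#' @param background Optional pre-built `markov_bg` to use instead of
#'   estimating one from `promoters`.
#' @return Pooled hit `data.frame` (see [scan_sequence()]).
#' @export
scan_promoters <- function(promoters, pfms, m = 2L, p_threshold = 1e-5,
                           pseudo_frequency = 0.001, granularity = 1e-3,
                           strands = c("both", "forward"), background = NULL) {
  strands <- match.arg(strands)
  empty <- data.frame(tf_id = character(0), motif_id = character(0),
                      gene_id = character(0), start = integer(0),
                      strand = character(0), matched_word = character(0),
                      score = numeric(0), pvalue = numeric(0))
  if (!length(pfms)) {
    warning("no PFMs supplied; returning zero hits", call. = FALSE)
    return(empty)
  }
  if (is.null(background)) background <- build_markov_background(promoters, m)
  res <- vector("list", length(pfms))
  for (k in seq_along(pfms)) {
    wm <- pfm_to_weight_matrix(pfms[[k]], background, pseudo_frequency)
    dist <- score_pvalue_table(wm, background, granularity)
    per_gene <- lapply(names(promoters), function(g) {
      scan_sequence(promoters[[g]], wm, background, dist,
                    p_threshold = p_threshold, strands = strands, gene_id = g)
    })
    res[[k]] <- do.call(rbind, per_gene)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[order(out$tf_id, out$motif_id, out$gene_id, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a binding-site hit table as TSV
#'
#' @param hits Hit `data.frame` from [scan_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding-site hit table written by [write_hits()]
#'
#' @param path Path to the TSV file.
#' @return Hit `data.frame`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(tf_id = "character", motif_id = "character",
                                   gene_id = "character", strand = "character",
                                   matched_word = "character"))
}
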