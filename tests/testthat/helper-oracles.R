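# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (brute force, enumeration, simulation) so that a
# bug cannot cancel out of both sides of a comparison.

BASES <- c("A", "C", "G", "T")

random_seqs <- function(n, len_range = c(10, 200)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  stats::setNames(
    vapply(lens, function(L) paste(sample(BASES, L, replace = TRUE),
                                   collapse = ""), character(1)),
    paste0("s", seq_len(n)))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive word enumeration: probability of each length-w word under the
# order-m chain (initial context from context_probs), plus its score bin sum.
enumerate_words <- function(dist, bg, w) {
  m <- bg$order
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  prob <- apply(grid, 1L, function(wd) {
    if (m == 0L) {
      p <- prod(bg$transition[1L, wd])
    } else {
      # marginalise over the initial context
      p <- 0
      K <- 4L^m
      for (c0 in seq_len(K)) {
        pc <- bg$context_probs[c0]
        ctx <- c0
        pw <- pc
        for (j in seq_len(w)) {
          pw <- pw * bg$transition[ctx, wd[j]]
          suffix <- (ctx - 1L) %% 4L^(m - 1L)
          ctx <- suffix * 4L + wd[j]
        }
        p <- p + pw
      }
    }
    p
  })
  binsum <- apply(grid, 1L, function(wd) sum(dist$wbin[cbind(seq_len(w), wd)]))
  list(prob = prob, binsum = binsum)
}

# Sample one length-n word from the background chain (used for empirical
# exceedance checks).
sample_bg_words <- function(bg, w, n_draws) {
  m <- bg$order
  K <- 4L^m
  out <- matrix(0L, nrow = n_draws, ncol = w)
  ctx <- sample.int(K, n_draws, replace = TRUE, prob = bg$context_probs)
  for (j in seq_len(w)) {
    b <- integer(n_draws)
    for (c0 in unique(ctx)) {
      sel <- ctx == c0
      b[sel] <- sample.int(4L, sum(sel), replace = TRUE,
                           prob = bg$transition[c0, ])
    }
    out[, j] <- b
    if (m > 0L) ctx <- ((ctx - 1L) %% 4L^(m - 1L)) * 4L + b
  }
  out
}

# Brute-force window rescoring oracle for scan_sequence.
oracle_scan <- function(seq, wm, dist, p_threshold, strands = "both") {
  w <- nrow(wm$weights)
  hits <- list()
  scan1 <- function(s, minus) {
    L <- nchar(s)
    if (L < w) return(NULL)
    for (i in seq_len(L - w + 1L)) {
      word <- substr(s, i, i + w - 1L)
      codes <- match(strsplit(word, "")[[1]], BASES)
      if (anyNA(codes)) next
      bs <- sum(dist$wbin[cbind(seq_len(w), codes)])
      pv <- dist$pvalue[bs - dist$minsum + 1L]
      if (pv <= p_threshold) {
        hits[[length(hits) + 1L]] <<- data.frame(
          start = if (minus) nchar(s) - i - w + 2L else i,
          strand = if (minus) "-" else "+", word = word, pvalue = pv)
      }
    }
  }
  scan1(seq, FALSE)
  if (strands == "both") scan1(oracle_revcomp(seq), TRUE)
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0),
                      word = character(0), pvalue = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# All-pairs BFS path-counting betweenness oracle (directed, endpoints
# excluded), independent of igraph: sigma_ij(n) = sigma(i,n) * sigma(n,j)
# whenever d(i,n) + d(n,j) = d(i,j).
oracle_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(u) {
    unique(edges$target[edges$tf == u & edges$target != u])
  })
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s0 in nodes) {
    dist[s0, s0] <- 0; sigma[s0, s0] <- 1
    frontier <- s0
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(dist[s0, v])) {
            dist[s0, v] <- dist[s0, u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[s0, v] == dist[s0, u] + 1) {
            sigma[s0, v] <- sigma[s0, v] + sigma[s0, u]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  B <- stats::setNames(numeric(n), nodes)
  for (i in nodes) for (j in nodes) {
    if (i == j || sigma[i, j] == 0) next
    for (v in nodes) {
      if (v == i || v == j) next
      if (is.finite(dist[i, v]) && is.finite(dist[v, j]) &&
          dist[i, v] + dist[v, j] == dist[i, j]) {
        B[v] <- B[v] + sigma[i, v] * sigma[v, j] / sigma[i, j]
      }
    }
  }
  B
}

# O(n^3) FFL oracle.
oracle_ffls <- function(nodes, edges) {
  has <- function(a, b) any(edges$tf == a & edges$target == b)
  out <- list()
  for (x in nodes) for (y in nodes) for (z in nodes) {
    if (x == y || y == z || x == z) next
    if (has(x, y) && has(x, z) && has(y, z)) {
      out[[length(out) + 1L]] <- data.frame(master = x, intermediate = y,
                                            target = z)
    }
  }
  if (!length(out)) {
    return(data.frame(master = character(0), intermediate = character(0),
                      target = character(0)))
  }
  o <- do.call(rbind, out)
  o <- o[order(o$master, o$intermediate, o$target), , drop = FALSE]
  rownames(o) <- NULL
  o
}

random_digraph_edges <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(tf = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tf != pairs$target, ]
  keep <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  rownames(keep) <- NULL
  list(nodes = nodes, edges = keep)
}

# Cached seed-17 regulatory fixture scan shared by the heavier tests.
fixture_cache <- new.env(parent = emptyenv())
seed17_scan <- function() {
  if (is.null(fixture_cache$scan)) {
    fx <- generate_regulatory_fixture(seed = 17)
    hits <- scan_promoters(fx$promoters, fx$pfms, m = 2, p_threshold = 1e-5)
    fixture_cache$scan <- list(fx = fx, hits = hits,
                               grn = build_grn(hits_to_interactions(hits)))
  }
  fixture_cache$scan
}
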