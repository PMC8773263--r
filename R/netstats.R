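#' Node outdegrees
#'
#' Number of distinct outgoing edges per node; self-loops count.
#'
#' @param grn A `grn`.
#' @return Named integer vector over all network nodes.
#' @export
node_outdegrees <- function(grn) {
  stopifnot(inherits(grn, "grn"))
  od <- table(factor(grn$edges$tf, levels = grn$nodes))
  stats::setNames(as.integer(od), grn$nodes)
}

#' Directed betweenness centrality, raw and min-max normalized
#'
#' `B(n) = sum over ordered pairs i != j != n of sigma_ij(n) / sigma_ij`,
#' where `sigma_ij` counts directed shortest paths from i to j and
#' `sigma_ij(n)` those passing through n (endpoints excluded); pairs with no
#' path contribute nothing. The normalized score is
#' `(B(n) - min B) / (max B - min B)`; when all raw scores are equal every
#' normalized score is 0. Self-loops never lie on a shortest path and are
#' ignored.
#'
#' @param grn A `grn`.
#' @return `data.frame` with columns `node`, `raw`, `normalized`.
#' @export
normalized_betweenness <- function(grn) {
  stopifnot(inherits(grn, "grn"))
  if (!length(grn$nodes)) {
    return(data.frame(node = character(0), raw = numeric(0),
                      normalized = numeric(0)))
  }
  g <- as_igraph(grn, drop_self_loops = TRUE)
  raw <- igraph::betweenness(g, directed = TRUE)
  raw <- raw[grn$nodes]
  rng <- range(raw)
  norm <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else raw * 0
  data.frame(node = grn$nodes, raw = unname(raw), normalized = unname(norm))
}

#' Enumerate feed-forward loops and tally node roles
#'
#' A feed-forward loop is an ordered triple of pairwise-distinct nodes
#' (x, y, z) with edges x->y, x->z and y->z: x is the master regulator, y the
#' intermediate and z the target. Self-loops are excluded by the
#' distinct-node requirement; 3-cycles and plain fan-outs are not counted.
#'
#' @param grn A `grn`.
#' @return List with `triples` (`data.frame`: `master`, `intermediate`,
#'   `target`) and `roles` (`data.frame` over all nodes with the three role
#'   counts).
#' @export
enumerate_ffls <- function(grn) {
  stopifnot(inherits(grn, "grn"))
  e <- grn$edges[grn$edges$tf != grn$edges$target, c("tf", "target")]
  out <- split(e$target, e$tf)
  trip <- list()
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      x <- e$tf[i]; y <- e$target[i]
      oy <- out[[y]]
      if (is.null(oy)) next
      z <- intersect(out[[x]], oy)
      z <- setdiff(z, c(x, y))
      if (length(z)) trip[[length(trip) + 1L]] <- data.frame(master = x,
                                                             intermediate = y,
                                                             target = z)
    }
  }
  triples <- if (length(trip)) do.call(rbind, trip) else
    data.frame(master = character(0), intermediate = character(0),
               target = character(0))
  triples <- triples[order(triples$master, triples$intermediate,
                           triples$target), , drop = FALSE]
  rownames(triples) <- NULL
  count_role <- function(v) {
    as.integer(table(factor(v, levels = grn$nodes)))
  }
  roles <- data.frame(node = grn$nodes,
                      ffl_master = count_role(triples$master),
                      ffl_intermediate = count_role(triples$intermediate),
                      ffl_target = count_role(triples$target))
  list(triples = triples, roles = roles)
}

#' Greedy accumulated-unique-coverage ranking of regulators
#'
#' Iteratively selects the candidate whose out-neighbour set adds the most
#' not-yet-covered nodes (self-loops count as covering the node itself).
#' Ties break by larger total outdegree, then lexicographic id, so the
#' ranking is a deterministic total order. Candidates are ranked to
#' exhaustion even after coverage gains reach zero.
#'
#' @param grn A `grn`.
#' @param candidates Candidate node set; defaults to all regulators
#'   (outdegree >= 1).
#' @return `data.frame` with one row per ranked candidate: `node`,
#'   `new_targets`, `cumulative_unique`, `cumulative_fraction` (of all
#'   network nodes).
#' @export
greedy_coverage_ranking <- function(grn, candidates = NULL) {
  stopifnot(inherits(grn, "grn"))
  od <- node_outdegrees(grn)
  if (is.null(candidates)) candidates <- names(od)[od >= 1L]
  candidates <- as.character(candidates)
  out <- split(grn$edges$target, grn$edges$tf)
  n_nodes <- length(grn$nodes)
  covered <- character(0)
  left <- sort(candidates)
  rows <- vector("list", length(left))
  for (step in seq_along(rows)) {
    gains <- vapply(left, function(tf) {
      length(setdiff(out[[tf]] %||% character(0), covered))
    }, integer(1))
    best_gain <- max(gains)
    pool <- left[gains == best_gain]
    pool <- pool[order(-od[pool], pool)]
    pick <- pool[1]
    covered <- union(covered, out[[pick]] %||% character(0))
    rows[[step]] <- data.frame(node = pick, new_targets = best_gain,
                               cumulative_unique = length(covered),
                               cumulative_fraction =
                                 if (n_nodes) length(covered) / n_nodes else 0)
    left <- setdiff(left, pick)
  }
  out_df <- do.call(rbind, rows) %||%
    data.frame(node = character(0), new_targets = integer(0),
               cumulative_unique = integer(0), cumulative_fraction = numeric(0))
  rownames(out_df) <- NULL
  out_df
}

#' Select key TFs: the shortest ranking prefix reaching target coverage
#'
#' @param ranking Output of [greedy_coverage_ranking()].
#' @param coverage_threshold Fraction of network nodes to cover
#'   (default 0.9).
#' @return Character vector of key TF ids. If the threshold is never reached
#'   the full ranking is returned with a warning.
#' @export
select_key_tfs <- function(ranking, coverage_threshold = 0.9) {
  stopifnot(is.data.frame(ranking))
  if (!nrow(ranking)) stop("empty ranking", call. = FALSE)
  assert_scalar_number(coverage_threshold, "coverage_threshold",
                       lower = 0, upper = 1)
  hit <- which(ranking$cumulative_fraction >= coverage_threshold)
  if (!length(hit)) {
    warning(sprintf("coverage never reaches %.2f; returning all %d ranked TFs",
                    coverage_threshold, nrow(ranking)), call. = FALSE)
    return(ranking$node)
  }
  ranking$node[seq_len(hit[1])]
}

#' Per-node measures table (outdegree, FFL roles, betweenness)
#'
#' Convenience join of [node_outdegrees()], [enumerate_ffls()] role counts
#' and [normalized_betweenness()], plus DEG directions when the network
#' carries them; the usual export alongside a key-regulator ranking.
#'
#' @param grn A `grn`.
#' @return `data.frame` sorted by decreasing outdegree.
#' @export
node_measures <- function(grn) {
  od <- node_outdegrees(grn)
  ffl <- enumerate_ffls(grn)$roles
  btw <- normalized_betweenness(grn)
  out <- data.frame(node = grn$nodes, outdegree = unname(od[grn$nodes]),
                    ffl[match(grn$nodes, ffl$node), -1, drop = FALSE],
                    betweenness_raw = btw$raw[match(grn$nodes, btw$node)],
                    betweenness_normalized =
                      btw$normalized[match(grn$nodes, btw$node)],
                    row.names = NULL)
  if (!is.null(grn$direction)) {
    out$deg_direction <- unname(grn$direction[out$node])
  }
  out[order(-out$outdegree, out$node), , drop = FALSE]
}
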