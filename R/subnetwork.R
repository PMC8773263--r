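#' Extract the DEG-induced (light-responsive) subnetwork
#'
#' Takes the subgraph induced on the differentially expressed nodes, then
#' removes nodes with total degree 0 inside it (a self-loop counts as
#' connectivity, so a self-regulating DEG survives). Each surviving node
#' carries its DEG direction.
#'
#' @param grn A `grn` (the genome-scale network).
#' @param degs Named character vector gene -> `"up"`/`"down"` (see
#'   [deg_directions()]), or a list with `up`/`down` vectors.
#' @return A `grn` restricted to connected DEG nodes, with `direction` set.
#' @export
extract_light_grn <- function(grn, degs) {
  stopifnot(inherits(grn, "grn"))
  if (is.list(degs) && !is.null(degs$up)) degs <- deg_directions(degs)
  deg_nodes <- names(degs)
  e <- grn$edges
  keep <- e$tf %in% deg_nodes & e$target %in% deg_nodes
  e <- e[keep, , drop = FALSE]
  nodes <- sort(unique(c(e$tf, e$target)))
  g <- build_grn(e, direction = degs[nodes])
  g$nodes <- nodes
  g
}

#' Label edges with the target gene's expression direction
#'
#' The putative regulation sign of an edge is taken from its target's DEG
#' direction; this is an annotation of the expression response, not a
#' mechanistic activation/repression claim.
#'
#' @param light_grn A `grn` whose nodes all carry a DEG direction.
#' @return The same `grn` with a `sign` column on the edges.
#' @export
annotate_edge_signs <- function(light_grn) {
  stopifnot(inherits(light_grn, "grn"))
  dir <- light_grn$direction
  if (is.null(dir)) stop("network has no DEG directions", call. = FALSE)
  sign <- unname(dir[light_grn$edges$target])
  if (anyNA(sign)) {
    bad <- light_grn$edges$target[which(is.na(sign))[1]]
    stop(sprintf("node '%s' has no DEG direction", bad), call. = FALSE)
  }
  light_grn$edges$sign <- sign
  light_grn
}

#' Extract a pathway subnetwork: listed genes plus their parent TFs
#'
#' Nodes are the listed genes present in the network plus their direct parent
#' regulators; edges are every network edge from those parents to the listed
#' genes, plus the edges among the included parents themselves (key-TF
#' interconnections stay visible).
#'
#' @param light_grn A `grn`.
#' @param gene_list Character vector of pathway gene ids.
#' @return A `grn` subgraph.
#' @export
extract_pathway_subnetwork <- function(light_grn, gene_list) {
  stopifnot(inherits(light_grn, "grn"))
  e <- light_grn$edges
  members <- intersect(gene_list, light_grn$nodes)
  parents <- unique(e$tf[e$target %in% members])
  nodes <- sort(union(members, parents))
  keep <- (e$tf %in% parents & e$target %in% members) |
    (e$tf %in% parents & e$target %in% parents)
  sub <- e[keep, , drop = FALSE]
  dir <- light_grn$direction
  g <- build_grn(sub, direction = if (!is.null(dir)) dir[intersect(nodes, names(dir))])
  g$nodes <- nodes
  g
}

#' Reciprocal-best-hit ortholog filter on tabular alignment hits
#'
#' Hits failing any threshold (`evalue <= max_evalue`,
#' `percent_identity >= min_identity`, `percent_coverage >= min_coverage`,
#' all inclusive) are dropped. A pair (q, s) is called an ortholog iff s is
#' q's best surviving forward hit and q is s's best surviving reverse hit;
#' "best" means maximum bitscore, ties broken by smaller evalue then
#' lexicographic subject id.
#'
#' @param forward,reverse `data.frame`s with columns `query_id`,
#'   `subject_id`, `evalue`, `percent_identity`, `percent_coverage`,
#'   `bitscore` (externally produced alignment summaries; whether coverage is
#'   query- or subject-side is up to the caller and should be documented).
#' @param max_evalue,min_identity,min_coverage Thresholds
#'   (defaults 1e-10, 60, 40).
#' @return `data.frame` with columns `query` and `subject`, sorted.
#' @export
rbh_ortholog_filter <- function(forward, reverse, max_evalue = 1e-10,
                                min_identity = 60, min_coverage = 40) {
  need <- c("query_id", "subject_id", "evalue", "percent_identity",
            "percent_coverage", "bitscore")
  for (nm in c("forward", "reverse")) {
    df <- get(nm)
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(sprintf("'%s' table missing column(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  surviving <- function(df) {
    df[df$evalue <= max_evalue & df$percent_identity >= min_identity &
         df$percent_coverage >= min_coverage, , drop = FALSE]
  }
  best_map <- function(df) {
    if (!nrow(df)) return(stats::setNames(character(0), character(0)))
    ord <- order(df$query_id, -df$bitscore, df$evalue, df$subject_id)
    df <- df[ord, , drop = FALSE]
    first <- !duplicated(df$query_id)
    stats::setNames(df$subject_id[first], df$query_id[first])
  }
  fb <- best_map(surviving(forward))
  rb <- best_map(surviving(reverse))
  q <- names(fb)
  ok <- !is.na(rb[fb]) & rb[fb] == q
  out <- data.frame(query = q[ok], subject = unname(fb[ok]))
  out <- out[order(out$query, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}
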