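#' Collapse binding-site hits into TF -> target interactions
#'
#' Hits from different motifs of the same TF, on either strand and at any
#' multiplicity, merge into a single interaction carrying the number of
#' contributing sites and the best (smallest) site p-value.
#'
#' @param hits `data.frame` of binding-site hits (columns `tf_id`, `gene_id`,
#'   and optionally `pvalue`), e.g. from [scan_promoters()].
#' @return `data.frame` with columns `tf`, `target`, `site_count`,
#'   `best_pvalue`, one row per distinct (tf, target) pair, sorted.
#' @export
hits_to_interactions <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) {
    return(data.frame(tf = character(0), target = character(0),
                      site_count = integer(0), best_pvalue = numeric(0)))
  }
  pv <- if ("pvalue" %in% names(hits)) hits$pvalue else rep(NA_real_, nrow(hits))
  key <- paste(hits$tf_id, hits$gene_id, sep = "\r")
  sc <- tapply(pv, key, length)
  bp <- suppressWarnings(tapply(pv, key, min))
  parts <- do.call(rbind, strsplit(names(sc), "\r", fixed = TRUE))
  out <- data.frame(tf = parts[, 1], target = parts[, 2],
                    site_count = as.integer(sc), best_pvalue = as.numeric(bp))
  out <- out[order(out$tf, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a directed gene regulatory network
#'
#' Nodes are every id appearing as a regulator or target; a node's role is
#' `regulator` when it has at least one outgoing edge, else `target`.
#' Self-loops are permitted (and reported separately in the summary).
#'
#' @param interactions `data.frame` with columns `tf` and `target` (optional
#'   `site_count`, `best_pvalue`), e.g. from [hits_to_interactions()].
#' @param direction Optional named character vector of per-node
#'   differential-expression directions (`"up"`/`"down"`).
#' @return An object of class `grn` with elements `edges` (data.frame),
#'   `nodes` (character) and `direction`.
#' @export
build_grn <- function(interactions, direction = NULL) {
  stopifnot(is.data.frame(interactions))
  edges <- as.data.frame(interactions)
  if (!nrow(edges)) {
    edges <- data.frame(tf = character(0), target = character(0),
                        site_count = integer(0), best_pvalue = numeric(0))
  }
  if (!all(c("tf", "target") %in% names(edges))) {
    stop("interactions need columns 'tf' and 'target'", call. = FALSE)
  }
  if (!"site_count" %in% names(edges)) edges$site_count <- rep(1L, nrow(edges))
  if (!"best_pvalue" %in% names(edges)) edges$best_pvalue <- rep(NA_real_, nrow(edges))
  if (anyDuplicated(edges[c("tf", "target")])) {
    stop("duplicate (tf, target) edges; collapse with hits_to_interactions() first",
         call. = FALSE)
  }
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$tf, edges$target)))
  structure(list(edges = edges, nodes = nodes, direction = direction),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<grn> %d nodes, %d edges, %d regulators\n",
              s$n_nodes, s$n_edges, s$n_regulators))
  invisible(x)
}

#' Summarise a gene regulatory network
#'
#' Mean and median outdegree are computed over regulators only (nodes with
#' outdegree >= 1), matching how genome-scale TF networks are usually
#' reported.
#'
#' @param object A `grn`.
#' @param ... Unused.
#' @return List with `n_nodes`, `n_edges`, `n_regulators`, `mean_outdegree`,
#'   `median_outdegree`, `n_self_loops`.
#' @method summary grn
#' @export
summary.grn <- function(object, ...) {
  od <- node_outdegrees(object)
  reg <- od[od >= 1L]
  list(n_nodes = length(object$nodes),
       n_edges = nrow(object$edges),
       n_regulators = length(reg),
       mean_outdegree = if (length(reg)) mean(reg) else NA_real_,
       median_outdegree = if (length(reg)) stats::median(reg) else NA_real_,
       n_self_loops = sum(object$edges$tf == object$edges$target))
}

as_igraph <- function(grn, drop_self_loops = FALSE) {
  e <- grn$edges
  if (drop_self_loops) e <- e[e$tf != e$target, , drop = FALSE]
  igraph::graph_from_data_frame(e[c("tf", "target")], directed = TRUE,
                                vertices = data.frame(name = grn$nodes))
}

#' Write a network as SIF or edge TSV
#'
#' The SIF dialect writes `regulator<TAB>regulates<TAB>target`, one edge per
#' line; `edge_tsv` writes a header plus `site_count`, `best_pvalue` and
#' `sign` columns when present. Edges are ordered lexicographically so output
#' is deterministic.
#'
#' @param grn A `grn`.
#' @param path Output path.
#' @param dialect `"sif"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(grn, path, dialect = c("edge_tsv", "sif")) {
  stopifnot(inherits(grn, "grn"))
  dialect <- match.arg(dialect)
  e <- grn$edges[order(grn$edges$tf, grn$edges$target), , drop = FALSE]
  if (dialect == "sif") {
    lines <- if (nrow(e)) paste(e$tf, "regulates", e$target, sep = "\t") else character(0)
    writeLines(lines, path)
  } else {
    cols <- intersect(c("tf", "target", "site_count", "best_pvalue", "sign"),
                      names(e))
    utils::write.table(e[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to a SIF or edge TSV file.
#' @param dialect `"sif"` or `"edge_tsv"`; default guesses from the
#'   extension (`.sif` vs anything else).
#' @return A `grn`.
#' @export
read_network <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "edge_tsv"
  }
  if (dialect == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(build_grn(data.frame(tf = character(0),
                                                    target = character(0))))
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    if (ncol(parts) != 3L || !all(parts[, 2] == "regulates")) {
      stop(sprintf("malformed SIF line in %s", path), call. = FALSE)
    }
    return(build_grn(data.frame(tf = parts[, 1], target = parts[, 3])))
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(tf = "character", target = "character"))
  build_grn(df)
}
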