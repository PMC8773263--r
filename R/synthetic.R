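# Fixed order-2 transition table used when background = "order2": a mildly
# structured chain (CG-suppressed, AT-rich runs damped) so the Markov
# background estimator has real signal to recover.
order2_transition <- function() {
  contexts <- all_contexts(2L)
  tr <- matrix(0.25, nrow = 16L, ncol = 4L,
               dimnames = list(contexts, DNA_BASES))
  tr[, "G"] <- ifelse(endsWith(contexts, "C"), 0.10, 0.28)
  tr[, "C"] <- ifelse(endsWith(contexts, "G"), 0.12, 0.26)
  tr[, "A"] <- ifelse(endsWith(contexts, "A"), 0.20, 0.24)
  tr[, "T"] <- ifelse(endsWith(contexts, "T"), 0.20, 0.24)
  tr / rowSums(tr)
}

sample_background_seq <- function(n, background) {
  if (background == "uniform") {
    return(paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""))
  }
  tr <- order2_transition()
  codes <- integer(n)
  codes[1:2] <- sample.int(4L, 2L, replace = TRUE)
  for (i in 3:n) {
    ctx <- (codes[i - 2L] - 1L) * 4L + codes[i - 1L]
    codes[i] <- sample.int(4L, 1L, prob = tr[ctx, ])
  }
  paste(DNA_BASES[codes], collapse = "")
}

#' Generate a promoter/motif fixture encoding a known regulatory network
#'
#' Builds the stated world every scanning and ranking stage is tested
#' against: a ground-truth GRN with `n_global_regulators` hub TFs each
#' targeting a large random fraction of all nodes (the few-key-regulators
#' regime) and the remaining TFs sparse; one PFM per TF with per-position
#' consensus probability `motif_sharpness` (off-consensus mass spread
#' evenly); and one promoter per node made of i.i.d. background letters with
#' one PFM-sampled site planted per true edge at a random non-overlapping
#' position and strand.
#'
#' The default motif length is 14 bp: at a site-calling threshold of
#' p <= 1e-5 the smallest attainable p-value for a width-w motif is ~4^-w,
#' so motifs shorter than 9 bp can never be called at all and at
#' sharpness 0.95 a width of 14 is needed before sites with up to two
#' sampling mismatches (~97% of planted sites) clear the threshold.
#'
#' @param n_tfs Total number of TFs (default 12).
#' @param n_genes Number of non-TF genes (default 150).
#' @param promoter_length Promoter length in bp (default 1000).
#' @param motif_length Motif width (default 14; see above).
#' @param motif_sharpness Consensus-base probability per position
#'   (default 0.95).
#' @param edge_density Per-(TF, node) edge probability for non-hub TFs
#'   (default 0.03).
#' @param n_global_regulators Number of hub TFs (default 3).
#' @param hub_target_fraction Per-node target probability for each hub.
#'   The default 0.55 is chosen so that, with three hubs, the expected
#'   accumulated unique coverage sits clearly below the usual 0.9 key-TF
#'   threshold after two hubs (~0.84) and clearly above it after all three
#'   (~0.96, once never-detected genes drop out of the node set), i.e. all
#'   and only the hubs are key regulators by construction.
#' @param background `"uniform"` (i.i.d. letters, default) or `"order2"`
#'   (letters from a fixed order-2 chain, to exercise the Markov background
#'   path).
#' @param seed Integer seed; the fixture is fully reproducible from it.
#' @return List with `promoters` (named character; one per node, TFs
#'   included), `pfms` (list of [pfm]) and `truth` (list: `true_edges`
#'   data.frame, `planted_sites` data.frame, `global_regulators`, `tf_ids`,
#'   `gene_ids`, `seed`).
#' @export
generate_regulatory_fixture <- function(n_tfs = 12L, n_genes = 150L,
                                        promoter_length = 1000L,
                                        motif_length = 14L,
                                        motif_sharpness = 0.95,
                                        edge_density = 0.03,
                                        n_global_regulators = 3L,
                                        hub_target_fraction = 0.55,
                                        background = c("uniform", "order2"),
                                        seed) {
  background <- match.arg(background)
  assert_scalar_number(n_tfs, "n_tfs", lower = 1)
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(motif_sharpness, "motif_sharpness", lower = 0.25, upper = 1)
  assert_scalar_number(edge_density, "edge_density", lower = 0, upper = 1)
  assert_scalar_number(hub_target_fraction, "hub_target_fraction",
                       lower = 0, upper = 1)
  assert_scalar_number(n_global_regulators, "n_global_regulators",
                       lower = 0, upper = n_tfs)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (motif_length > promoter_length) {
    stop("motif longer than promoter", call. = FALSE)
  }
  set.seed(seed)

  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  nodes <- c(tf_ids, gene_ids)
  hubs <- tf_ids[seq_len(n_global_regulators)]

  edges <- list()
  for (tf in tf_ids) {
    others <- setdiff(nodes, tf)
    p <- if (tf %in% hubs) hub_target_fraction else edge_density
    tgt <- others[stats::runif(length(others)) < p]
    if (length(tgt)) edges[[tf]] <- data.frame(tf = tf, gene = tgt)
  }
  true_edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf = character(0), gene = character(0))
  rownames(true_edges) <- NULL

  pfms <- lapply(tf_ids, function(tf) {
    consensus <- sample.int(4L, motif_length, replace = TRUE)
    probs <- matrix((1 - motif_sharpness) / 3, nrow = motif_length, ncol = 4L)
    probs[cbind(seq_len(motif_length), consensus)] <- motif_sharpness
    pfm(probs, tf_id = tf, motif_id = paste0(tf, "_M1"))
  })
  names(pfms) <- tf_ids

  promoters <- stats::setNames(
    vapply(nodes, function(x) sample_background_seq(promoter_length, background),
           character(1)),
    nodes)

  # plant one PFM-sampled site per true edge, non-overlapping per promoter
  sites <- list()
  w <- motif_length
  for (node in nodes) {
    inc <- true_edges[true_edges$gene == node, , drop = FALSE]
    if (!nrow(inc)) next
    taken <- integer(0)
    for (i in seq_len(nrow(inc))) {
      tf <- inc$tf[i]
      probs <- pfms[[tf]]$probs
      word <- paste(DNA_BASES[vapply(seq_len(w), function(j) {
        sample.int(4L, 1L, prob = probs[j, ])
      }, integer(1))], collapse = "")
      repeat {
        pos <- sample.int(promoter_length - w + 1L, 1L)
        if (!any(abs(pos - taken) < w)) break
      }
      taken <- c(taken, pos)
      strand <- sample(c("+", "-"), 1L)
      insert <- if (strand == "+") word else revcomp(word)
      promoters[[node]] <- paste0(substr(promoters[[node]], 1L, pos - 1L),
                                  insert,
                                  substr(promoters[[node]], pos + w,
                                         promoter_length))
      sites[[length(sites) + 1L]] <- data.frame(tf = tf, gene = node,
                                                position = pos,
                                                strand = strand, word = word)
    }
  }
  planted_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(tf = character(0), gene = character(0), position = integer(0),
               strand = character(0), word = character(0))
  rownames(planted_sites) <- NULL

  list(promoters = promoters, pfms = unname(pfms),
       truth = list(true_edges = true_edges, planted_sites = planted_sites,
                    global_regulators = hubs, tf_ids = tf_ids,
                    gene_ids = gene_ids, seed = as.integer(seed)))
}

#' Generate a two-condition count fixture with planted DEGs
#'
#' Baseline expression is log-normal (sdlog 1), scaled so the expected
#' library depth equals `depth`; one library per condition is drawn
#' negative-binomially with the given dispersion (counts are overdispersed
#' beyond the multinomial technical noise the DEG caller simulates, on
#' purpose). A `deg_fraction` subset of genes has its condition-1 mean
#' multiplied (first half) or divided (second half) by `fold_change`.
#'
#' @param n_genes Number of genes (default 1000).
#' @param depth Expected library depth (default 2e6).
#' @param deg_fraction Fraction of genes planted as DEGs (default 0.05).
#' @param fold_change True fold change of planted DEGs (default 8).
#' @param dispersion Negative-binomial dispersion (1/size; default 0.1).
#' @param seed Integer seed.
#' @param conditions Two condition labels (default `c("light", "dark")`;
#'   condition 1 gets the fold changes).
#' @return List with `counts` (a [count_table] with samples `light_1`,
#'   `dark_1`) and `truth` (named `true_degs` direction vector,
#'   `true_fold_changes`, `seed`). `fold_change = 1` yields an empty truth
#'   DEG set.
#' @export
generate_counts_fixture <- function(n_genes = 1000L, depth = 2e6,
                                    deg_fraction = 0.05, fold_change = 8,
                                    dispersion = 0.1, seed,
                                    conditions = c("light", "dark")) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(depth, "depth", lower = 1)
  assert_scalar_number(deg_fraction, "deg_fraction", lower = 0, upper = 1,
                       closed_upper = FALSE)
  assert_scalar_number(fold_change, "fold_change", lower = 0, closed_lower = FALSE)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(length(conditions) == 2L)
  set.seed(seed)

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  mu <- baseline / sum(baseline) * depth

  n_deg <- round(deg_fraction * n_genes)
  deg_idx <- if (n_deg) sample.int(n_genes, n_deg) else integer(0)
  fc <- rep(1, n_genes)
  if (n_deg) {
    up <- deg_idx[seq_len(ceiling(n_deg / 2))]
    down <- setdiff(deg_idx, up)
    fc[up] <- fold_change
    fc[down] <- 1 / fold_change
  }

  mu1 <- mu * fc
  mu2 <- mu
  size <- if (dispersion > 0) 1 / dispersion else Inf
  draw <- function(mm) {
    if (is.finite(size)) stats::rnbinom(n_genes, mu = mm, size = size)
    else stats::rpois(n_genes, mm)
  }
  counts <- cbind(draw(mu1), draw(mu2))
  dimnames(counts) <- list(gene_ids, paste0(conditions, "_1"))
  ct <- count_table(counts, stats::setNames(conditions, colnames(counts)))

  is_deg <- fc != 1
  true_degs <- stats::setNames(ifelse(fc[is_deg] > 1, "up", "down"),
                               gene_ids[is_deg])
  list(counts = ct,
       truth = list(true_degs = true_degs,
                    true_fold_changes = stats::setNames(fc, gene_ids),
                    seed = as.integer(seed)))
}

#' Write a fixture bundle to disk
#'
#' Writes everything the pipeline needs (promoters FASTA, per-TF PFM files,
#' counts TSV) plus the ground-truth tables, so a generated bundle can drive
#' the full pipeline with no other inputs.
#'
#' @param regulatory Fixture from [generate_regulatory_fixture()], or `NULL`.
#' @param counts Fixture from [generate_counts_fixture()], or `NULL`.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(regulatory = NULL, counts = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory %s", dir),
                             call. = FALSE)
  paths <- list()
  if (!is.null(regulatory)) {
    paths$promoters <- file.path(dir, "promoters.fasta")
    write_fasta(regulatory$promoters, paths$promoters)
    pfm_dir <- file.path(dir, "pfms")
    dir.create(pfm_dir, showWarnings = FALSE)
    for (p in regulatory$pfms) {
      write_cisbp_pfm(p, file.path(pfm_dir, paste0(p$motif_id, ".txt")))
    }
    paths$pfms <- pfm_dir
    paths$truth_edges <- file.path(dir, "truth_edges.tsv")
    utils::write.table(regulatory$truth$true_edges, paths$truth_edges,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truth_sites <- file.path(dir, "truth_sites.tsv")
    utils::write.table(regulatory$truth$planted_sites, paths$truth_sites,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths$global_regulators <- file.path(dir, "global_regulators.txt")
    writeLines(regulatory$truth$global_regulators, paths$global_regulators)
  }
  if (!is.null(counts)) {
    paths$counts <- file.path(dir, "counts.tsv")
    write_counts_table(counts$counts, paths$counts)
    paths$truth_degs <- file.path(dir, "truth_degs.tsv")
    td <- counts$truth$true_degs
    utils::write.table(data.frame(gene_id = names(td), direction = unname(td)),
                       paths$truth_degs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
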