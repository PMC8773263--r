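#' Pipeline configuration
#'
#' Validates and freezes every tunable of the scan -> build -> deg ->
#' extract -> rank pipeline. Defaults are the published operating point:
#' order-2 Markov background, site p-value 1e-5, minimum 5 reads per gene,
#' simulated-replicate parameters pnr 0.2 / nss 10 / v 0.02, DEG probability
#' 0.9 and key-TF coverage 0.9.
#'
#' @param promoters Path to the promoter FASTA.
#' @param pfms Path to a PFM file or directory.
#' @param counts Optional path to a two-sample count TSV.
#' @param condition_map Named character vector sample -> condition (required
#'   with `counts`).
#' @param gene_lists Optional named list of pathway gene-list file paths.
#' @param out_dir Output directory.
#' @param markov_order,pvalue_threshold,min_reads,pnr,nss,v,q_threshold,coverage_threshold
#'   Stage parameters (see module functions for meaning).
#' @param seed Integer seed controlling the DEG simulation.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(promoters, pfms, counts = NULL,
                            condition_map = NULL, gene_lists = NULL,
                            out_dir, markov_order = 2L,
                            pvalue_threshold = 1e-5, min_reads = 5L,
                            pnr = 0.2, nss = 10L, v = 0.02,
                            q_threshold = 0.9, coverage_threshold = 0.9,
                            seed) {
  assert_scalar_number(markov_order, "markov_order", lower = 0)
  assert_scalar_number(pvalue_threshold, "pvalue_threshold", lower = 0,
                       upper = 1, closed_lower = FALSE)
  assert_scalar_number(min_reads, "min_reads", lower = 0)
  assert_scalar_number(q_threshold, "q_threshold", lower = 0, upper = 1)
  assert_scalar_number(coverage_threshold, "coverage_threshold",
                       lower = 0, upper = 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  params <- sim_params(pnr = pnr, nss = nss, v = v, seed = seed)
  if (!is.null(counts) && is.null(condition_map)) {
    stop("'condition_map' is required when counts are supplied", call. = FALSE)
  }
  structure(list(promoters = promoters, pfms = pfms, counts = counts,
                 condition_map = condition_map, gene_lists = gene_lists,
                 out_dir = out_dir, markov_order = as.integer(markov_order),
                 pvalue_threshold = pvalue_threshold,
                 min_reads = as.integer(min_reads), sim = params,
                 q_threshold = q_threshold,
                 coverage_threshold = coverage_threshold,
                 seed = as.integer(seed)),
        class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys are [pipeline_config()] arguments.
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  if (!is.null(vals$condition_map)) vals$condition_map <- unlist(vals$condition_map)
  do.call(pipeline_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full inference pipeline
#'
#' Stages: promoter scanning, genome-scale GRN assembly, (optionally)
#' filtering + TMM + simulated-replicate DEG calling, light-responsive
#' subnetwork extraction with edge signs, node measures and greedy
#' key-regulator ranking, and per-list pathway subnetworks. All tables are
#' written under `config$out_dir` together with a JSON manifest recording
#' every parameter, input checksum and the seed; a one-line summary of
#' node/edge/TF/DEG counts is printed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress the summary message (default `FALSE`).
#' @return List with `grn`, `degs` (or `NULL`), `light_grn`, `measures`,
#'   `ranking`, `key_tfs`, `summary` and `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  promoters <- run_stage("read_promoters", read_fasta(config$promoters))
  pfms <- run_stage("read_pfms", read_cisbp_pfms(config$pfms))

  hits <- run_stage("scan", scan_promoters(promoters, pfms,
                                           m = config$markov_order,
                                           p_threshold = config$pvalue_threshold))
  paths$hits <- file.path(config$out_dir, "hits.tsv")
  write_hits(hits, paths$hits)

  grn <- run_stage("build", build_grn(hits_to_interactions(hits)))
  paths$grn <- file.path(config$out_dir, "grn.tsv")
  write_network(grn, paths$grn, "edge_tsv")
  paths$grn_sif <- file.path(config$out_dir, "grn.sif")
  write_network(grn, paths$grn_sif, "sif")

  degs <- NULL
  light <- grn
  if (!is.null(config$counts)) {
    degs <- run_stage("deg", {
      ct <- read_counts_table(config$counts, config$condition_map)
      ct <- filter_low_counts(ct, config$min_reads)
      norm <- tmm_normalize(ct)
      noiseq_sim(ct, norm, config$sim, q_threshold = config$q_threshold)
    })
    paths$degs <- file.path(config$out_dir, "degs.tsv")
    write_deg_table(degs, paths$degs)
    light <- run_stage("extract", {
      lg <- extract_light_grn(grn, deg_directions(call_degs(degs,
                                                            config$q_threshold)))
      if (nrow(lg$edges)) lg <- annotate_edge_signs(lg)
      lg
    })
    paths$light_grn <- file.path(config$out_dir, "light_grn.tsv")
    write_network(light, paths$light_grn, "edge_tsv")
  }

  measures <- run_stage("rank", node_measures(light))
  ranking <- run_stage("rank", greedy_coverage_ranking(light))
  key_tfs <- if (nrow(ranking)) {
    run_stage("rank", select_key_tfs(ranking, config$coverage_threshold))
  } else character(0)
  paths$measures <- file.path(config$out_dir, "measures.tsv")
  utils::write.table(measures, paths$measures, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$ranking <- file.path(config$out_dir, "ranking.tsv")
  utils::write.table(ranking, paths$ranking, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$key_tfs <- file.path(config$out_dir, "key_tfs.txt")
  writeLines(key_tfs, paths$key_tfs)

  if (!is.null(config$gene_lists)) {
    for (nm in names(config$gene_lists)) {
      sub <- run_stage("pathway", {
        extract_pathway_subnetwork(light, read_gene_list(config$gene_lists[[nm]]))
      })
      p <- file.path(config$out_dir, sprintf("subnetwork_%s.tsv", nm))
      write_network(sub, p, "edge_tsv")
      paths[[paste0("subnetwork_", nm)]] <- p
    }
  }

  gs <- summary(grn)
  ls_ <- summary(light)
  summary_line <- sprintf(
    paste0("genome GRN: %d sites, %d interactions, %d nodes, %d regulators | ",
           "%s: %d nodes, %d edges, %d TFs | key TFs: %s"),
    nrow(hits), gs$n_edges, gs$n_nodes, gs$n_regulators,
    if (is.null(degs)) "ranked network" else
      sprintf("light GRN (%d up / %d down DEGs)",
              sum(degs$direction == "up"), sum(degs$direction == "down")),
    ls_$n_nodes, ls_$n_edges, ls_$n_regulators,
    paste(key_tfs, collapse = ", "))
  if (!quiet) message(summary_line)

  inputs <- c(promoters = config$promoters, pfms = config$pfms,
              counts = config$counts %||% character(0),
              unlist(config$gene_lists))
  input_files <- inputs[file.exists(inputs) & !dir.exists(inputs)]
  manifest <- list(
    parameters = list(markov_order = config$markov_order,
                      pvalue_threshold = config$pvalue_threshold,
                      min_reads = config$min_reads,
                      pnr = config$sim$pnr, nss = config$sim$nss,
                      v = config$sim$v, q_threshold = config$q_threshold,
                      coverage_threshold = config$coverage_threshold,
                      seed = config$seed),
    inputs = as.list(tools::md5sum(input_files)),
    outputs = lapply(paths, basename),
    summary = summary_line)
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(grn = grn, degs = degs, light_grn = light, measures = measures,
       ranking = ranking, key_tfs = key_tfs, summary = summary_line,
       paths = paths)
}
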