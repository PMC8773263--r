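#' Remove genes with fewer than `min_reads` reads everywhere
#'
#' A gene is retained iff its maximum count across samples reaches
#' `min_reads` (default 5). Gene order is preserved.
#'
#' @param counts A [count_table].
#' @param min_reads Minimum read count (default 5).
#' @return A filtered [count_table].
#' @export
filter_low_counts <- function(counts, min_reads = 5L) {
  stopifnot(inherits(counts, "count_table"))
  assert_scalar_number(min_reads, "min_reads", lower = 0)
  keep <- apply(counts$counts, 1L, max) >= min_reads
  count_table(counts$counts[keep, , drop = FALSE], counts$conditions)
}

#' TMM scaling-factor normalization
#'
#' Trimmed mean of M-values, the standard composition-bias correction for
#' count libraries: the reference sample is the one whose upper-quartile
#' count fraction is closest to the mean; per-sample log2 fold changes (M)
#' and average log intensities (A) against the reference, over genes with
#' positive counts in both, are doubly trimmed (`trim_M` on M, `trim_A` on
#' A) and averaged with inverse binomial-variance weights; factors are
#' rescaled so their geometric mean is exactly 1.
#'
#' @param counts A [count_table] (>= 2 samples, no all-zero sample).
#' @param trim_M Two-sided trim fraction on M (default 0.30).
#' @param trim_A Two-sided trim fraction on A (default 0.05).
#' @return List of class `tmm_norm` with `factors` (named, geometric mean 1),
#'   `effective_library_size` (library size x factor) and `reference`.
#' @export
tmm_normalize <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(counts, "count_table"))
  y <- counts$counts
  if (ncol(y) < 2L) stop("TMM needs at least two samples", call. = FALSE)
  lib <- colSums(y)
  if (any(lib == 0)) {
    stop(sprintf("sample '%s' has all-zero counts", colnames(y)[lib == 0][1]),
         call. = FALSE)
  }
  f75 <- apply(y, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(k) {
    if (k == ref) return(1)
    obs <- y[, k]; nref <- y[, ref]
    pos <- obs > 0 & nref > 0
    obs <- obs[pos]; nref <- nref[pos]
    if (!length(obs)) return(1)
    Nk <- lib[k]; Nr <- lib[ref]
    M <- log2((obs / Nk) / (nref / Nr))
    A <- 0.5 * log2((obs / Nk) * (nref / Nr))
    v <- (Nk - obs) / (Nk * obs) + (Nr - nref) / (Nr * nref)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep) || all(v[keep] == 0)) return(1)
    f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f)) return(1)
    2^f
  }

  factors <- vapply(seq_len(ncol(y)), one_factor, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(y)
  structure(list(factors = factors,
                 effective_library_size = lib * factors,
                 reference = colnames(y)[ref]),
            class = "tmm_norm")
}

#' Parameters of the simulated-technical-replicate DEG caller
#'
#' @param pnr Fraction of the library depth drawn per simulated replicate
#'   (default 0.2).
#' @param nss Number of simulated replicates per condition (default 10).
#' @param v Half-width of the uniform jitter on simulated totals, as a
#'   fraction of depth; must satisfy `0 <= v < pnr` (default 0.02).
#' @param seed Integer seed; required, because the DEG table is stochastic
#'   and irreproducible without one.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(pnr = 0.2, nss = 10L, v = 0.02, seed) {
  assert_scalar_number(pnr, "pnr", lower = 0, upper = 1, closed_lower = FALSE)
  assert_scalar_number(nss, "nss", lower = 1)
  if (nss != round(nss)) stop("'nss' must be an integer", call. = FALSE)
  assert_scalar_number(v, "v", lower = 0, upper = pnr, closed_upper = FALSE)
  if (missing(seed)) stop("'seed' is required for a reproducible DEG table",
                          call. = FALSE)
  assert_scalar_number(seed, "seed", lower = -2^31 + 10, upper = 2^31 - 10)
  structure(list(pnr = pnr, nss = as.integer(nss), v = v,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' No-replicate differential expression via simulated technical replicates
#'
#' For a design with exactly one library per condition, technical replicates
#' are simulated per condition: `nss` multinomial draws over genes with
#' probabilities proportional to the condition's TMM-normalized counts and
#' totals uniform on `[(pnr - v) N, (pnr + v) N]` (N = that library's raw
#' depth). Replicates are scaled to counts-per-million, zeros replaced by
#' `k_zero`, and each gene's signal is `M = log2(mean_1 / mean_2)`,
#' `D = |mean_1 - mean_2|` (condition 1 is the condition of the first sample
#' column). The noise distribution pools `(|M|, D)` over all within-condition
#' replicate pairs and all genes; a gene's differential-expression
#' probability `q` is the fraction of noise pairs strictly dominated in both
#' coordinates. Deterministic given `params$seed`.
#'
#' @param counts A [count_table] with exactly one sample per condition (two
#'   conditions). More replicates are an error: use a replicate-aware method.
#' @param norm A `tmm_norm` for the same samples.
#' @param params A [sim_params].
#' @param k_zero Value replacing zeros after CPM scaling (default 0.5).
#' @param q_threshold Threshold used to fill the `direction` column
#'   (default 0.9).
#' @return `data.frame` of class `deg_table`: `gene_id`, `mean_cond1`,
#'   `mean_cond2`, `M`, `D`, `q`, `direction`; attribute `conditions` gives
#'   the (cond1, cond2) labels.
#' @export
noiseq_sim <- function(counts, norm, params, k_zero = 0.5, q_threshold = 0.9) {
  stopifnot(inherits(counts, "count_table"), inherits(norm, "tmm_norm"),
            inherits(params, "sim_params"))
  assert_scalar_number(k_zero, "k_zero", lower = 0, closed_lower = FALSE)
  y <- counts$counts
  cond <- counts$conditions
  if (length(unique(cond)) != 2L || ncol(y) != 2L) {
    stop(paste("noiseq_sim handles exactly one sample per condition (two",
               "conditions); with replicates use a replicate-aware method"),
         call. = FALSE)
  }
  G <- nrow(y)
  lib <- colSums(y)

  # Each sample's draws are keyed to its name, not its column position, so
  # presenting the swapped design (dark first) reproduces the same per-sample
  # replicates and flips M exactly (label-swap antisymmetry).
  cpm_reps <- vector("list", 2L)
  for (k in 1:2) {
    set.seed(params$seed + match(colnames(y)[k], sort(colnames(y))))
    probs <- y[, k] / norm$factors[k]
    if (sum(probs) == 0) stop("a sample with all-zero counts cannot be simulated",
                              call. = FALSE)
    probs <- probs / sum(probs)
    totals <- round(stats::runif(params$nss,
                                 (params$pnr - params$v) * lib[k],
                                 (params$pnr + params$v) * lib[k]))
    reps <- vapply(totals, function(tt) stats::rmultinom(1L, tt, probs)[, 1],
                   numeric(G))
    cpm <- sweep(reps, 2L, colSums(reps), `/`) * 1e6
    cpm[cpm == 0] <- k_zero
    cpm_reps[[k]] <- cpm
  }

  cond1 <- cond[1]; cond2 <- cond[2]
  mean1 <- rowMeans(cpm_reps[[1]])
  mean2 <- rowMeans(cpm_reps[[2]])
  M <- log2(mean1 / mean2)
  D <- abs(mean1 - mean2)

  noise_M <- numeric(0); noise_D <- numeric(0)
  for (k in 1:2) {
    cpm <- cpm_reps[[k]]
    pairs <- utils::combn(params$nss, 2L)
    for (p in seq_len(ncol(pairs))) {
      a <- cpm[, pairs[1, p]]; b <- cpm[, pairs[2, p]]
      noise_M <- c(noise_M, abs(log2(a / b)))
      noise_D <- c(noise_D, abs(a - b))
    }
  }

  absM <- abs(M)
  q <- vapply(seq_len(G), function(g) {
    mean(absM[g] > noise_M & D[g] > noise_D)
  }, numeric(1))

  direction <- rep("none", G)
  direction[q >= q_threshold & M > 0] <- "up"
  direction[q >= q_threshold & M < 0] <- "down"

  out <- data.frame(gene_id = rownames(y), mean_cond1 = mean1,
                    mean_cond2 = mean2, M = M, D = D, q = q,
                    direction = direction, row.names = NULL)
  attr(out, "conditions") <- c(cond1, cond2)
  attr(out, "params") <- unclass(params)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Partition DEG records into up- and down-regulated gene sets
#'
#' @param records A `deg_table` from [noiseq_sim()].
#' @param q_threshold Differential-expression probability cutoff
#'   (default 0.9).
#' @return List with character vectors `up` (q >= threshold, M > 0) and
#'   `down` (q >= threshold, M < 0).
#' @export
call_degs <- function(records, q_threshold = 0.9) {
  stopifnot(is.data.frame(records))
  assert_scalar_number(q_threshold, "q_threshold", lower = 0, upper = 1)
  ok <- records$q >= q_threshold
  list(up = records$gene_id[ok & records$M > 0],
       down = records$gene_id[ok & records$M < 0])
}

#' Turn DEG calls into a named direction vector
#'
#' @param degs List with `up`/`down` character vectors (from [call_degs()]).
#' @return Named character vector gene -> `"up"`/`"down"`.
#' @export
deg_directions <- function(degs) {
  stats::setNames(c(rep("up", length(degs$up)), rep("down", length(degs$down))),
                  c(degs$up, degs$down))
}

#' Write a DEG table as TSV
#'
#' @param records A `deg_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
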