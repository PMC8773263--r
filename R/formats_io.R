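#' Read a FASTA file into a named sequence set
#'
#' Sequences are upper-cased and validated against the `A,C,G,T,N` alphabet.
#' Unlike a bare FASTA reader this refuses duplicate identifiers, empty
#' records and non-nucleotide characters (reported with their position)
#' instead of silently coercing.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (a `SequenceSet`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate sequence identifier in %s: '%s'", path, dup[1]),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop(sprintf("empty sequence for identifier '%s'", ids[empty[1]]),
         call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("non-nucleotide character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]),
         call. = FALSE)
  }
  seqs
}

#' Write a named sequence set to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# ---- CIS-BP style PFM tables ------------------------------------------------

#' Read CIS-BP style PFM text files
#'
#' The layout is optional metadata lines (`TF<TAB>id`, `Motif<TAB>id`),
#' a header line `Pos A C G T`, then one row per motif position with the four
#' base probabilities. One file holds one motif; when no metadata lines are
#' present the file name (without extension) supplies both ids.
#'
#' @param path A single PFM file or a directory of `.txt` PFM files.
#' @return A list of [pfm] objects.
#' @export
read_cisbp_pfms <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop(sprintf("no .txt PFM files in %s", path), call. = FALSE)
    return(lapply(files, read_cisbp_pfm_file))
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  list(read_cisbp_pfm_file(path))
}

read_cisbp_pfm_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  default_id <- sub("\\.[^.]*$", "", basename(file))
  tf_id <- default_id
  motif_id <- default_id
  i <- 1L
  while (i <= length(lines) && !grepl("^Pos\\b", lines[i])) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] == "TF") tf_id <- parts[2]
    if (length(parts) == 2L && parts[1] == "Motif") motif_id <- parts[2]
    i <- i + 1L
  }
  if (i > length(lines)) {
    stop(sprintf("no 'Pos A C G T' header in %s", file), call. = FALSE)
  }
  body <- lines[-seq_len(i)]
  if (!length(body)) stop(sprintf("PFM in %s has no positions", file), call. = FALSE)
  rows <- lapply(body, function(ln) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
    if (length(vals) != 5L || anyNA(vals)) {
      stop(sprintf("malformed PFM row in %s: '%s'", file, ln), call. = FALSE)
    }
    vals[-1L]
  })
  pfm(do.call(rbind, rows), tf_id = tf_id, motif_id = motif_id)
}

#' Write a PFM in CIS-BP text layout
#'
#' @param x A [pfm] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cisbp_pfm <- function(x, path) {
  stopifnot(inherits(x, "pfm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("TF\t", x$tf_id), paste0("Motif\t", x$motif_id),
               "Pos\tA\tC\tG\tT"), con)
  for (i in seq_len(nrow(x$probs))) {
    writeLines(paste(c(i, sprintf("%.10g", x$probs[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

# ---- Upstream (promoter) extraction -----------------------------------------

#' Extract upstream regions from a genome
#'
#' Returns, for each annotated gene, the `length` bases immediately 5' of the
#' gene start on the coding strand (positions -1 to -`length`): for a `+`
#' strand gene the slice `start - length .. start - 1`, for a `-` strand gene
#' the reverse complement of `end + 1 .. end + length`. Windows are truncated
#' at contig boundaries; genes whose window is empty are omitted with a
#' warning. Coordinates are 1-based and fully closed.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotations `data.frame` with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand` (`+`/`-`), 1-based inclusive coordinates.
#' @param length Upstream window size in bp (default 1000).
#' @return Named character vector of upstream sequences, names = gene ids.
#' @export
extract_upstream <- function(genome, annotations, length = 1000L) {
  stopifnot(is.character(genome), is.data.frame(annotations))
  need <- c("gene_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(annotations))
  if (base::length(miss)) {
    stop(sprintf("annotations missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  assert_scalar_number(length, "length", lower = 1)
  if (!all(annotations$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  absent <- setdiff(unique(annotations$contig), names(genome))
  if (base::length(absent)) {
    stop(sprintf("annotation on missing contig: %s", absent[1]), call. = FALSE)
  }
  clen <- nchar(genome)
  bad <- with(annotations, start < 1 | start > end | end > clen[contig])
  if (any(bad)) {
    stop(sprintf("invalid coordinates for gene '%s'",
                 annotations$gene_id[which(bad)[1]]), call. = FALSE)
  }
  out <- character(0)
  dropped <- character(0)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (a$strand == "+") {
      from <- max(1L, a$start - length)
      to <- a$start - 1L
      if (to < from) { dropped <- c(dropped, a$gene_id); next }
      out[a$gene_id] <- substr(genome[[a$contig]], from, to)
    } else {
      from <- a$end + 1L
      to <- min(clen[[a$contig]], a$end + length)
      if (to < from) { dropped <- c(dropped, a$gene_id); next }
      out[a$gene_id] <- revcomp(substr(genome[[a$contig]], from, to))
    }
  }
  if (base::length(dropped)) {
    warning(sprintf("omitted %d gene(s) with empty upstream window: %s",
                    base::length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  out
}

# ---- Count tables -----------------------------------------------------------

#' Two-condition read-count table
#'
#' @param counts Integer matrix, rows = genes (rownames required), columns =
#'   samples (colnames required); no negative values.
#' @param conditions Character vector naming each sample's condition, named by
#'   sample or in column order.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs row (gene) and column (sample) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (any(counts != round(counts))) stop("counts must be integers", call. = FALSE)
  if (is.null(names(conditions))) {
    if (length(conditions) != ncol(counts)) {
      stop("one condition per sample required", call. = FALSE)
    }
    names(conditions) <- colnames(counts)
  }
  unmapped <- setdiff(colnames(counts), names(conditions))
  if (length(unmapped)) {
    stop(sprintf("sample '%s' has no condition assigned", unmapped[1]), call. = FALSE)
  }
  structure(list(counts = counts,
                 conditions = as.character(conditions[colnames(counts)])),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%s", colnames(x$counts), x$conditions),
                    collapse = ", ")))
  invisible(x)
}

#' Read a TSV gene-count table
#'
#' First column is the gene id; remaining columns are per-sample integer
#' counts. Non-integer or negative cells are an error naming the offending
#' row and column.
#'
#' @param path Path to the TSV file.
#' @param condition_map Named character vector `sample -> condition`.
#' @return A [count_table].
#' @export
read_counts_table <- function(path, condition_map) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("count table needs a gene column and >= 1 sample", call. = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene id: '%s'", genes[duplicated(genes)][1]), call. = FALSE)
  }
  samples <- names(df)[-1]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("non-integer count at row %d (gene '%s'), column '%s': '%s'",
                   bad[1], genes[bad[1]], samples[j], df[[j + 1L]][bad[1]]),
           call. = FALSE)
    }
    mat[, j] <- v
  }
  unmapped <- setdiff(samples, names(condition_map))
  if (length(unmapped)) {
    stop(sprintf("sample '%s' missing from condition_map", unmapped[1]), call. = FALSE)
  }
  count_table(mat, condition_map[samples])
}

#' Write a count table as TSV
#'
#' @param ct A [count_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  df <- data.frame(gene_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path Path to the list file; blank lines and `#` comments ignored.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
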