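test_that("read_fasta parses, validates and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT"), tmp)
  expect_identical(read_fasta(tmp), c(g1 = "ACGT"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0L)

  # round-trip of 50 random records, lengths 10-200
  set.seed(7)
  seqs <- random_seqs(50)
  rt <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, rt)
  expect_identical(read_fasta(rt), seqs)

  # malformed inputs carry ids / positions
  dup <- withr::local_tempfile()
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_fasta(dup), "duplicate.*'a'")
  bad <- withr::local_tempfile()
  writeLines(c(">a", "ACXT"), bad)
  expect_error(read_fasta(bad), "position 3")
  blank <- withr::local_tempfile()
  writeLines(c(">a", "", ">b", "ACGT"), blank)
  expect_error(read_fasta(blank), "empty sequence")
})

test_that("CIS-BP PFM reader validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT",
               "1\t1\t0\t0\t0", "2\t0\t1\t0\t0",
               "3\t0\t0\t1\t0", "4\t0\t0\t0\t1"), f)
  p <- read_cisbp_pfms(f)[[1]]
  expect_s3_class(p, "pfm")
  expect_equal(nrow(p$probs), 4L)
  expect_identical(pfm_consensus(p), "ACGT")

  expect_equal(unname(pfm(matrix(0.25, 1, 4), "t")$probs[1, ]), rep(0.25, 4))

  # round-trip of a random length-8 PFM preserves entries to 1e-9
  set.seed(3)
  probs <- matrix(stats::rgamma(32, 1), 8, 4)
  probs <- probs / rowSums(probs)
  orig <- pfm(probs, "TFX", "TFX_M2")
  rt <- withr::local_tempfile(fileext = ".txt")
  write_cisbp_pfm(orig, rt)
  back <- read_cisbp_pfms(rt)[[1]]
  expect_identical(back$tf_id, "TFX")
  expect_identical(back$motif_id, "TFX_M2")
  expect_equal(back$probs, orig$probs, tolerance = 1e-9)

  # bad row sums and empty matrices rejected
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT", "1\t2\t1\t0\t0"), bad)
  expect_error(read_cisbp_pfms(bad), "outside")
  expect_error(pfm(matrix(numeric(0), 0, 4), "t"), "at least one position")
})

test_that("extract_upstream follows the -1..-1000 coding-strand convention", {
  set.seed(11)
  genome <- c(chr1 = paste(sample(BASES, 3000, replace = TRUE), collapse = ""))
  ann <- data.frame(gene_id = "gA", contig = "chr1", start = 2001, end = 3000,
                    strand = "+")
  up <- extract_upstream(genome, ann, 1000)
  expect_identical(unname(up["gA"]), substr(genome[[1]], 1001, 2000))

  # gene starting at position 1 has an empty window and is omitted
  ann2 <- rbind(ann, data.frame(gene_id = "gB", contig = "chr1", start = 1,
                                end = 10, strand = "+"))
  expect_warning(up2 <- extract_upstream(genome, ann2, 1000), "empty upstream")
  expect_identical(names(up2), "gA")

  # 20 random genes on random 5-kb contigs vs a slice/revcomp oracle
  contigs <- stats::setNames(
    replicate(4, paste(sample(BASES, 5000, replace = TRUE), collapse = "")),
    paste0("c", 1:4))
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    contig = sample(names(contigs), 20, replace = TRUE),
    start = sample(500:4500, 20), strand = sample(c("+", "-"), 20, TRUE))
  genes$end <- pmin(genes$start + sample(100:400, 20), 5000L)
  up3 <- extract_upstream(contigs, genes, 300)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    expected <- if (g$strand == "+") {
      substr(contigs[[g$contig]], max(1, g$start - 300), g$start - 1)
    } else {
      oracle_revcomp(substr(contigs[[g$contig]], g$end + 1,
                            min(5000, g$end + 300)))
    }
    expect_identical(unname(up3[g$gene_id]), expected, label = g$gene_id)
    expect_lte(nchar(up3[g$gene_id]), 300)
  }

  # strand mirror property: minus-strand extraction equals revcomp-genome
  # plus-strand extraction of the mirrored gene
  g <- genes[genes$strand == "-", ][1, ]
  L <- nchar(contigs[[g$contig]])
  mirrored <- data.frame(gene_id = g$gene_id, contig = g$contig,
                         start = L - g$end + 1, end = L - g$start + 1,
                         strand = "+")
  rc_genome <- stats::setNames(oracle_revcomp(contigs[g$contig]), g$contig)
  expect_identical(unname(up3[g$gene_id]),
                   unname(extract_upstream(rc_genome, mirrored, 300)[g$gene_id]))

  expect_error(extract_upstream(genome,
                                data.frame(gene_id = "x", contig = "nope",
                                           start = 1, end = 2, strand = "+")),
               "missing contig")
})

test_that("count-table reader validates cells and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t3\t4", "g2\t0\t9"), tmp)
  ct <- read_counts_table(tmp, c(s1 = "light", s2 = "dark"))
  expect_identical(dim(ct$counts), c(2L, 2L))
  expect_identical(ct$conditions, c("light", "dark"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t3\t-4"), bad)
  expect_error(read_counts_table(bad, c(s1 = "a", s2 = "b")),
               "row 1.*column 's2'")
  expect_error(read_counts_table(tmp, c(s1 = "light")), "condition_map")

  # round-trip of a random 100 x 4 table
  set.seed(5)
  m <- matrix(rpois(400, 50), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  ct2 <- count_table(m, stats::setNames(c("a", "a", "b", "b"), colnames(m)))
  rt <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(ct2, rt)
  back <- read_counts_table(rt, stats::setNames(ct2$conditions, colnames(m)))
  expect_identical(back$counts, ct2$counts * 1)  # numeric storage
  expect_identical(back$conditions, ct2$conditions)
})

test_that("network writers are deterministic and round-trip", {
  grn <- build_grn(data.frame(tf = c("B", "A"), target = c("C", "B"),
                              site_count = c(2L, 1L),
                              best_pvalue = c(1e-6, 1e-8)))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(grn, sif, "sif")
  expect_identical(readLines(sif),
                   c("A\tregulates\tB", "B\tregulates\tC"))

  # empty network: empty SIF, header-only TSV
  empty <- build_grn(data.frame(tf = character(0), target = character(0)))
  e1 <- withr::local_tempfile(fileext = ".sif")
  write_network(empty, e1, "sif")
  expect_identical(readLines(e1), character(0))
  e2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(empty, e2, "edge_tsv")
  expect_length(readLines(e2), 1L)

  # 200-edge random network round-trips through both dialects
  set.seed(23)
  g <- random_digraph_edges(30, 0.25)
  big <- build_grn(g$edges)
  for (dialect in c("sif", "edge_tsv")) {
    f <- withr::local_tempfile(fileext = if (dialect == "sif") ".sif" else ".tsv")
    write_network(big, f, dialect)
    back <- read_network(f)
    expect_identical(back$edges[c("tf", "target")],
                     big$edges[c("tf", "target")])
  }
})

test_that("gene lists read one id per line, ignoring comments", {
  f <- withr::local_tempfile()
  writeLines(c("# pathway", "g1", "", "g2", "g1"), f)
  expect_identical(read_gene_list(f), c("g1", "g2"))
})
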