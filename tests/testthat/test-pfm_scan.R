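test_that("Markov background matches direct counts", {
  # strand-pooled order-0 hand example: "AAAC" + revcomp "GTTT"
  bg <- build_markov_background(c(x = "AAAC"), m = 0, pseudo_count = 0)
  expect_equal(unname(bg$stationary), c(3, 1, 1, 3) / 8)
  bg_f <- build_markov_background(c(x = "AAAC"), m = 0, pseudo_count = 0,
                                  pool_strands = FALSE)
  expect_equal(unname(bg_f$stationary), c(0.75, 0.25, 0, 0))

  bg2 <- build_markov_background(c(x = "AAAA"), m = 2, pseudo_count = 0,
                                 pool_strands = FALSE)
  expect_equal(bg2$transition["AA", "A"], 1)

  # random 10-kb sequence vs a hash-count oracle
  set.seed(13)
  s <- paste(sample(BASES, 10000, replace = TRUE), collapse = "")
  bg3 <- build_markov_background(c(s = s), m = 2, pseudo_count = 1)
  expect_true(all(abs(rowSums(bg3$transition) - 1) < 1e-12))
  chars <- strsplit(s, "")[[1]]
  rc <- strsplit(oracle_revcomp(s), "")[[1]]
  count_oracle <- function(ctx, b) {
    n <- 0
    for (cs in list(chars, rc)) {
      tri <- paste0(cs[1:(length(cs) - 2)], cs[2:(length(cs) - 1)],
                    cs[3:length(cs)])
      n <- n + sum(tri == paste0(ctx, b))
    }
    n
  }
  for (ctx in c("AA", "CG", "TC")) {
    tot <- sum(vapply(BASES, function(b) count_oracle(ctx, b), numeric(1)))
    for (b in c("A", "T")) {
      expect_equal(bg3$transition[ctx, b],
                   (count_oracle(ctx, b) + 1) / (tot + 4))
    }
  }
  expect_error(build_markov_background(c(x = "ACGT"), m = -1), "non-negative")
})

test_that("weight matrices follow the pseudo-frequency log-ratio formula", {
  bg <- structure(list(order = 0L,
                       transition = matrix(0.25, 1, 4,
                                           dimnames = list("", BASES)),
                       context_probs = c(1), stationary =
                         stats::setNames(rep(0.25, 4), BASES)),
                  class = "markov_bg")
  p1 <- pfm(matrix(c(1, 0, 0, 0), 1, 4), "t")
  wm <- pfm_to_weight_matrix(p1, bg, 0.001)
  expect_equal(unname(wm$weights[1, "A"]), log(1.001 / 1.004) - log(0.25),
               tolerance = 1e-12)
  uniform <- pfm_to_weight_matrix(pfm(matrix(0.25, 1, 4), "t"), bg, 0.001)
  expect_equal(unname(uniform$weights[1, ]),
               rep(log((0.25 + 0.001) / 1.004 / 0.25), 4), tolerance = 1e-12)

  # normalization identity: sum_b exp(weight) * stationary(b) = 1
  set.seed(99)
  for (rep in 1:5) {
    probs <- matrix(stats::rgamma(20, 1), 5, 4)
    probs <- probs / rowSums(probs)
    stat <- stats::rgamma(4, 1); stat <- stat / sum(stat)
    bg2 <- bg; bg2$stationary <- stats::setNames(stat, BASES)
    w <- pfm_to_weight_matrix(pfm(probs, "t"), bg2)$weights
    expect_equal(unname(rowSums(exp(w) %*% diag(stat))), rep(1, 5),
                 tolerance = 1e-12)
  }
  expect_error(pfm_to_weight_matrix(p1, bg, 0), "pseudo_frequency")
})

test_that("score distribution equals exhaustive enumeration (m = 0 and m = 1)", {
  set.seed(21)
  for (m in 0:1) {
    w <- if (m == 0) 4L else 5L
    seqs <- c(s = paste(sample(BASES, 4000, replace = TRUE, prob = c(.3, .2, .2, .3)),
                        collapse = ""))
    bg <- build_markov_background(seqs, m = m)
    probs <- matrix(stats::rgamma(4 * w, 1), w, 4)
    probs <- probs / rowSums(probs)
    wm <- pfm_to_weight_matrix(pfm(probs, "t"), bg)
    dist <- score_pvalue_table(wm, bg)
    enum <- enumerate_words(dist, bg, w)
    expect_equal(sum(enum$prob), 1, tolerance = 1e-12)
    for (s in sort(unique(enum$binsum))) {
      expect_equal(dist$pvalue[s - dist$minsum + 1],
                   sum(enum$prob[enum$binsum >= s]), tolerance = 1e-9,
                   label = sprintf("pvalue at bin %d (m=%d)", s, m))
    }
  }
})

test_that("p-values are monotone, bounded and 1 at the minimum score", {
  set.seed(31)
  seqs <- c(s = paste(sample(BASES, 5000, replace = TRUE), collapse = ""))
  bg <- build_markov_background(seqs, m = 2)
  probs <- matrix(stats::rgamma(24, 1), 6, 4); probs <- probs / rowSums(probs)
  dist <- score_pvalue_table(pfm_to_weight_matrix(pfm(probs, "t"), bg), bg)
  expect_true(all(diff(dist$pvalue) <= 1e-15))
  expect_true(all(dist$pvalue > 0 & dist$pvalue <= 1))
  expect_equal(dist$pvalue[1], 1, tolerance = 1e-12)
})

test_that("empirical exceedance under the background never beats the p-value", {
  # conservativeness at p ~ 1e-3 with 20,000 chain draws
  set.seed(43)
  seqs <- c(s = paste(sample(BASES, 8000, replace = TRUE, prob = c(.35, .15, .15, .35)),
                      collapse = ""))
  bg <- build_markov_background(seqs, m = 2)
  probs <- matrix(0.05 / 3, 6, 4)
  probs[cbind(1:6, sample.int(4, 6, TRUE))] <- 0.95
  probs <- probs / rowSums(probs)
  wm <- pfm_to_weight_matrix(pfm(probs, "t"), bg)
  dist <- score_pvalue_table(wm, bg)
  target_bin <- dist$minsum + which.min(abs(dist$pvalue - 1e-3)) - 1L
  pv <- dist$pvalue[target_bin - dist$minsum + 1L]
  words <- sample_bg_words(bg, 6L, 20000L)
  bins <- rowSums(matrix(dist$wbin[cbind(rep(1:6, each = 20000),
                                         as.vector(words))], ncol = 6))
  emp <- mean(bins >= target_bin)
  se <- sqrt(pv * (1 - pv) / 20000)
  expect_lte(emp, pv + 3 * se)
})

test_that("scan_sequence matches the window-rescoring oracle and is strand-symmetric", {
  set.seed(2)
  seqs <- c(s = paste(sample(BASES, 6000, replace = TRUE), collapse = ""))
  bg <- build_markov_background(seqs, m = 1)
  probs <- matrix(stats::rgamma(20, 1), 5, 4); probs <- probs / rowSums(probs)
  wm <- pfm_to_weight_matrix(pfm(probs, "t"), bg)
  dist <- score_pvalue_table(wm, bg)

  # 100 random sequences, permissive threshold so hits actually occur
  for (i in 1:100) {
    L <- sample(20:120, 1)
    sq <- paste(sample(c(BASES, "N"), L, replace = TRUE,
                       prob = c(rep(0.24, 4), 0.04)), collapse = "")
    got <- scan_sequence(sq, wm, bg, dist, p_threshold = 0.02)
    want <- oracle_scan(sq, wm, dist, 0.02)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$start, want$start)
      expect_identical(got$strand, want$strand)
      expect_identical(got$matched_word, want$word)
      expect_equal(got$pvalue, want$pvalue, tolerance = 1e-12)
    }
  }

  # strand symmetry: hits on revcomp(seq) mirror the hits on seq
  sq <- paste(sample(BASES, 200, replace = TRUE), collapse = "")
  h1 <- scan_sequence(sq, wm, bg, dist, p_threshold = 0.05)
  h2 <- scan_sequence(oracle_revcomp(sq), wm, bg, dist, p_threshold = 0.05)
  L <- nchar(sq); w <- 5L
  mirrored <- data.frame(start = L - h2$start - w + 2L,
                         strand = ifelse(h2$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(h1$start, mirrored$start)
  expect_equal(h1$strand, mirrored$strand)

  expect_identical(nrow(scan_sequence("", wm, bg, dist)), 0L)
  expect_identical(nrow(scan_sequence("ACG", wm, bg, dist)), 0L)
})

test_that("a planted near-degenerate TGACA site is found exactly once", {
  # the 5-bp homeodomain-like consensus cannot clear p <= 1e-5 (4^-5 floor),
  # so this planted-site check runs at the smallest attainable level
  set.seed(2)
  backbone <- paste(sample(BASES, 200, replace = TRUE), collapse = "")
  # scrub chance consensus occurrences so the planted site is unique
  for (word in c("TGACA", "TGTCA")) {
    while ((i <- regexpr(word, backbone, fixed = TRUE)) > 0) {
      substr(backbone, i + 2L, i + 2L) <- "C"
    }
  }
  probs <- matrix(0.01, 5, 4)
  consensus <- match(c("T", "G", "A", "C", "A"), BASES)
  probs[cbind(1:5, consensus)] <- 0.97
  probs <- probs / rowSums(probs)
  bg <- build_markov_background(c(b = backbone), m = 0)
  wm <- pfm_to_weight_matrix(pfm(probs, "homeo"), bg)
  dist <- score_pvalue_table(wm, bg)
  pos <- 101L
  planted <- paste0(substr(backbone, 1, pos - 1), "TGACA",
                    substr(backbone, pos + 5, 200))
  thr <- min(dist$pvalue) * 1.0000001
  hits <- scan_sequence(planted, wm, bg, dist, p_threshold = thr)
  hits <- hits[hits$strand == "+", ]
  expect_identical(hits$start, pos)
  expect_identical(hits$matched_word, "TGACA")
})

test_that("site calling at 1e-5 is impossible below 9 bp of motif", {
  # documents the discrete floor: min p-value ~ 4^-w
  set.seed(6)
  seqs <- c(s = paste(sample(BASES, 4000, replace = TRUE), collapse = ""))
  bg <- build_markov_background(seqs, m = 0)
  probs <- matrix(0.05 / 3, 8, 4)
  probs[cbind(1:8, sample.int(4, 8, TRUE))] <- 0.95
  dist <- score_pvalue_table(pfm_to_weight_matrix(pfm(probs, "t"), bg), bg)
  expect_gt(min(dist$pvalue), 1e-5)
})

test_that("scan_promoters pools hits, recovers planted sites and stays quiet on noise", {
  sc <- seed17_scan()
  truth <- sc$fx$truth
  hit_keys <- unique(paste(sc$hits$tf_id, sc$hits$gene_id))
  site_keys <- paste(truth$planted_sites$tf, truth$planted_sites$gene)
  expect_gte(mean(site_keys %in% hit_keys), 0.9)

  expect_warning(z <- scan_promoters(c(p = "ACGTACGT"), list()), "no PFMs")
  expect_identical(nrow(z), 0L)

  # false-positive bound on unplanted promoters:
  # mean hits per strand per PFM <= 10 * (L - w + 1) * p_threshold
  set.seed(77)
  L <- 300L
  proms <- stats::setNames(
    replicate(200, paste(sample(BASES, L, replace = TRUE), collapse = "")),
    sprintf("p%03d", 1:200))
  probs <- matrix(0.05 / 3, 10, 4)
  probs[cbind(1:10, sample.int(4, 10, TRUE))] <- 0.95
  pf <- pfm(probs / rowSums(probs), "noisefree")
  hits <- scan_promoters(proms, list(pf), m = 2, p_threshold = 1e-5)
  per_strand_per_pfm <- nrow(hits) / 2
  expect_lte(per_strand_per_pfm / 200, 10 * (L - 10 + 1) * 1e-5)
})
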