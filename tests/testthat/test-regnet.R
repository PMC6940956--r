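test_that("MEME minimal parsing validates and preserves motif order", {
  motifs <- packaged_motifs()
  expect_length(motifs, 5)
  expect_identical(vapply(motifs, `[[`, "", "id"),
                   c("gbox_core", "abre_like", "myb_core", "gata_box",
                     "wbox_core"))
  expect_identical(motifs[[1]]$family, "bZIP")
  for (m in motifs) {
    expect_true(all(abs(rowSums(m$matrix) - 1) < 1e-9))
    expect_true(all(m$matrix > 0))
  }
  # single degenerate column gets the pseudocount
  m1 <- pwm("one", matrix(c(1, 0, 0, 0), 1, 4))
  expect_equal(unname(m1$matrix[1, "A"]), (1 + 1e-4) / (1 + 4e-4),
               tolerance = 1e-12)

  bad <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "ALPHABET= ACGT", "MOTIF broken",
               "letter-probability matrix: alength= 4 w= 1",
               "0.5 0.1 0.1 0.1"), bad)
  expect_error(read_meme_motifs(bad), "sum to")
  writeLines(c("MEME version 4", "ALPHABET= ACGU", "MOTIF rna",
               "letter-probability matrix: alength= 4 w= 1",
               "0.25 0.25 0.25 0.25"), bad)
  expect_error(read_meme_motifs(bad), "not DNA")
})

test_that("MEME write/read round-trips the probability matrices", {
  motifs <- packaged_motifs()
  path <- tempfile(fileext = ".meme")
  write_meme_motifs(motifs, path)
  back <- read_meme_motifs(path)
  for (i in seq_along(motifs)) {
    expect_equal(back[[i]]$matrix, motifs[[i]]$matrix, tolerance = 5e-4)
    expect_identical(back[[i]]$id, motifs[[i]]$id)
  }
})

test_that("degenerate dinucleotide motif scores 4 bits with exact p 1/16", {
  m <- pwm("ac", consensus_matrix("AC"))
  expect_equal(pwm_score_pvalue(m, 4.0), 1 / 16, tolerance = 1e-12)
  hits <- scan_sequence(m, "GGACGG", p_threshold = 0.1)
  best <- hits[hits$offset == 2 & hits$strand == "+", ]
  expect_equal(best$score_bits, 4.0, tolerance = 1e-9)
  expect_equal(best$p, 1 / 16, tolerance = 1e-12)
})

test_that("DP p-values equal exhaustive enumeration for all packaged motifs", {
  for (m in packaged_motifs()) {
    enum <- enumerate_word_scores(m$matrix)
    svals <- sort(unique(enum$scores))
    p_dp <- pwm_score_pvalue(m, svals * 1e-3)
    p_enum <- vapply(svals, function(s) enum_tail(enum, s), numeric(1))
    expect_equal(p_dp, p_enum, tolerance = 1e-9, label = m$id)
  }
})

test_that("higher scores never get larger p-values", {
  for (m in packaged_motifs()[1:2]) {
    s <- seq(-10, 12, by = 0.25)
    p <- pwm_score_pvalue(m, s)
    expect_true(all(diff(p) <= 1e-15))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("scanning respects strand symmetry and skips N windows", {
  m <- packaged_motifs()[[1]]
  set.seed(7)
  seq_fwd <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
  hits_f <- scan_sequence(m, seq_fwd, p_threshold = 0.05, seq_id = "s",
                          collapse_overlaps = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
  hits_r <- scan_sequence(m, rc, p_threshold = 0.05, seq_id = "s",
                          collapse_overlaps = FALSE)
  # same hit set with strands swapped and offsets mirrored
  L <- nrow(m$matrix)
  mirror <- data.frame(offset = nchar(seq_fwd) - L - hits_r$offset,
                       strand = ifelse(hits_r$strand == "+", "-", "+"),
                       score_bits = hits_r$score_bits)
  o1 <- hits_f[order(hits_f$offset, hits_f$strand),
               c("offset", "strand", "score_bits")]
  o2 <- mirror[order(mirror$offset, mirror$strand), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, tolerance = 1e-9)

  with_n <- paste0(substr(seq_fwd, 1, 50), "N", substr(seq_fwd, 52, 300))
  hits_n <- scan_sequence(m, with_n, p_threshold = 1,
                          collapse_overlaps = FALSE)
  expect_false(any(hits_n$offset %in% (50 - L + 1):50 &
                     hits_n$strand == "+"))
  # motif longer than sequence: empty result, not an error
  expect_identical(nrow(scan_sequence(m, "ACG")), 0L)
  expect_error(scan_sequence(m, "ACGT", background = c(0, 0.5, 0.25, 0.25)),
               "> 0")
})

test_that("planted consensus sites are found at the planted position", {
  m <- pwm("site", consensus_matrix("TTGACCGA"))
  sim <- simulate_promoter_set(
    n_seqs = 3, length = 500,
    planted = list(planted_site(m, 1, 120, "+"),
                   planted_site(m, 3, 400, "-")),
    seed = 11)
  hits <- scan_promoters(list(m), sim$sequences, p_threshold = 1e-3)
  expect_true(any(hits$seq == "promoter001" & hits$offset == 120 &
                    hits$strand == "+"))
  expect_true(any(hits$seq == "promoter003" & hits$offset == 400 &
                    hits$strand == "-"))
})

test_that("pair designation joins TFs, motifs and targets", {
  hits <- data.frame(motif = c("m1", "m1", "m2"),
                     seq = c("tgt1", "tgt2", "tgt1"),
                     offset = c(10L, 20L, 30L), strand = "+",
                     score_bits = 8, p = 1e-5, q = 1e-4)
  motif2tf <- data.frame(motif = c("m1", "m2"), tf_gene = c("tfA", "tfB"))
  tf_degs <- data.frame(gene = c("tfA", "tfB"), fc = c(-3.5, 2.1),
                        fdr = c(1e-4, 1e-3), family = c("bZIP", "NAC"),
                        description = c("bZIP factor", "NAC factor"))
  target_degs <- data.frame(gene = c("tgt1", "tgt2"), fc = c(-10, -5),
                            fdr = c(1e-6, 1e-5),
                            description = c("PsbO", "LHCB1"))
  pairs <- designate_pairs(tf_degs, hits, motif2tf, target_degs)
  expect_identical(nrow(pairs), 3L)
  expect_identical(pairs$tf_gene, c("tfA", "tfA", "tfB"))  # sorted by TF FC
  expect_true(all(pairs$n_hits == 1))
  # a TF with two targets yields two pairs
  expect_identical(sum(pairs$tf_gene == "tfA"), 2L)
  # empty TF set -> no pairs
  none <- designate_pairs(tf_degs[0, ], hits, motif2tf, target_degs)
  expect_identical(nrow(none), 0L)
  # unmapped motif raises a warning and is ignored
  hits2 <- rbind(hits, data.frame(motif = "mX", seq = "tgt1", offset = 1L,
                                  strand = "+", score_bits = 5, p = 1e-4,
                                  q = 1e-3))
  expect_warning(p2 <- designate_pairs(tf_degs, hits2, motif2tf, target_degs),
                 "without a TF assignment")
  expect_identical(nrow(p2), 3L)
})

test_that("pair summaries reproduce the packaged 17-pair table", {
  pairs <- read_pairs_table()
  summ <- summarize_pairs(pairs)
  expect_identical(summ$total, 17L)
  expect_identical(summ$by_family[["bZIP"]], 6L)
  expect_identical(summ$by_family[["MYB_related"]], 3L)
  expect_identical(summ$by_direction[["up"]], 8L)
  expect_identical(summ$by_direction[["down"]], 9L)
  # totals conserved
  expect_identical(sum(summ$by_family), summ$total)
  expect_identical(sum(summ$by_direction), as.integer(summ$total))
  empty <- summarize_pairs(read_pairs_table()[0, ])
  expect_identical(empty$total, 0L)
  expect_identical(sum(empty$by_direction), 0L)
})

test_that("TF share of DEGs rounds to whole percent", {
  expect_identical(tf_deg_percent(1438, 1762, 2408), 34L)
  expect_identical(tf_deg_percent(0, 10, 10), 0L)
  expect_error(tf_deg_percent(5, 0, 0), "positive")
})
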