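test_that("per-motif minimum repeat thresholds are respected", {
  cfg <- scan_config()
  hit <- scan_sequence(strrep("A", 10), cfg)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$repeat_count, 10L)
  expect_equal(hit$category, "perfect")
  expect_equal(nrow(scan_sequence(strrep("A", 9), cfg)), 0L)
  expect_equal(nrow(scan_sequence(strrep("TG", 5), cfg)), 0L)
  expect_equal(nrow(scan_sequence(strrep("TG", 6), cfg)), 1L)
})

test_that("an embedded dinucleotide run is recovered with motif and count", {
  s <- paste0("GCGTACTGCA", strrep("TG", 12), "ACGTCCATGA")
  hit <- scan_sequence(s)
  expect_equal(hit$motif, "TG")
  expect_equal(hit$repeat_count, 12L)
  expect_equal(hit$start, 10L)       # 0-based
  expect_equal(hit$end, 34L)         # half-open; 24 bp span
})

test_that("runs are reported at their shortest period", {
  # (AT)9 is a dinucleotide run, never a tetra- or hexanucleotide one
  hit <- scan_sequence(paste0("GCCGA", strrep("AT", 9), "GCCGA"))
  expect_equal(hit$motif_length, 2L)
  expect_equal(hit$motif, "AT")
})

test_that("a single short interruption yields one imperfect locus", {
  s <- paste0(strrep("CT", 7), "AA", strrep("CT", 7))
  hit <- scan_sequence(s, scan_config(max_interruption_bp = 2))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$category, "imperfect")
  expect_equal(hit$motif, "CT")
  expect_equal(hit$repeat_count, 14L)
  expect_equal(c(hit$start, hit$end), c(0L, 30L))
  # with no interruption allowance and no compound merging the two runs
  # stay separate perfect loci
  hit0 <- scan_sequence(s, scan_config(max_interruption_bp = 0,
                                       compound_max_spacer_bp = 1))
  expect_equal(hit0$category, c("perfect", "perfect"))
})

test_that("nearby loci of different motifs merge into a compound locus", {
  s <- paste0("GACGATCGCA", strrep("CT", 7), "GACGA", strrep("TG", 8),
              "CATCATGCAA")
  hit <- scan_sequence(s)
  expect_equal(hit$category, "compound")
  expect_equal(hit$motif, "(CT)7(TG)8")
  # far apart: two separate perfect loci, one contig counted once
  far <- paste0(strrep("CT", 7), random_seq(150, 1), strrep("TG", 8))
  hits <- scan_sequence(far, scan_config(compound_max_spacer_bp = 20))
  expect_gte(nrow(hits), 2L)
  expect_true(all(hits$category == "perfect"))
})

test_that("N breaks runs and illegal characters are rejected with a position", {
  expect_equal(nrow(scan_sequence(strrep("N", 120))), 0L)
  split_run <- paste0(strrep("A", 6), "N", strrep("A", 6))
  expect_equal(nrow(scan_sequence(split_run)), 0L)
  expect_error(scan_sequence("ACGTXACGT"), "position 5")
})

test_that("reported loci never overlap and use 0-based half-open coordinates", {
  cfg <- scan_config()
  for (seed in 1:20) {
    s <- random_seq(2000, seed)
    # salt with a couple of real repeats
    s <- paste0(s, strrep("AAG", 6), random_seq(200, seed + 1000),
                strrep("CA", 8))
    hits <- scan_sequence(s, cfg)
    if (nrow(hits) > 1L) {
      hits <- hits[order(hits$start), ]
      expect_true(all(hits$start[-1] >= hits$end[-nrow(hits)]))
    }
    perf <- hits[hits$category == "perfect", ]
    expect_true(all(perf$end - perf$start ==
                      perf$motif_length * perf$repeat_count))
  }
})

test_that("the vectorised scanner matches the naive reference scanner", {
  cfg <- scan_config()
  for (seed in 1:30) {
    s <- random_seq(2000, 100 + seed)
    expect_identical(scan_sequence(s, cfg), scan_sequence_naive(s, cfg))
  }
  # also on repeat-dense sequences
  dense <- paste0(strrep("A", 11), "GC", strrep("GT", 7), "TTACG",
                  strrep("CTG", 6), "N", strrep("AT", 9))
  expect_identical(scan_sequence(dense, cfg), scan_sequence_naive(dense, cfg))
})

test_that("FASTA scanning validates input and counts contigs once", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", paste0(strrep("TG", 7),
                             paste(rep("GACTR", 0), collapse = ""),
                             random_seq(150, 3), strrep("TG", 7)),
               ">c2", random_seq(80, 4)), tmp)
  res <- scan_fasta(tmp, scan_config(compound_max_spacer_bp = 20))
  expect_equal(res$n_contigs, 2L)
  expect_lte(res$n_contigs_with_ssr, 2L)
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), dup)
  expect_error(scan_fasta(dup), "duplicate")
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(scan_fasta(empty), "empty|no such|read")
})

test_that("summary arithmetic reproduces published-style frequencies", {
  counts <- c(124L, 308L, 123L, 7L, 0L, 1L)
  loci <- do.call(rbind, lapply(1:6, function(k) {
    if (counts[k] == 0) return(NULL)
    data.frame(contig = sprintf("k%d_%d", k, seq_len(counts[k])),
               start = 0L, end = 20L, motif = strrep("A", k),
               motif_length = k, repeat_count = 10L, category = "perfect",
               stringsAsFactors = FALSE)
  }))
  extra <- data.frame(
    contig = c(sprintf("cmp%d", 1:59), sprintf("imp%d", 1:14)),
    start = 0L, end = 30L, motif = "X", motif_length = 2L, repeat_count = 10L,
    category = rep(c("compound", "imperfect"), c(59, 14)),
    stringsAsFactors = FALSE
  )
  all_loci <- rbind(loci, extra)
  sm <- summarize_ssr(all_loci, 636)
  expect_equal(sm$n_loci, 636L)
  expect_equal(unname(sm$category_counts), c(563L, 59L, 14L))
  expect_equal(unname(sm$perfect_freq_pct),
               c(19.50, 48.43, 19.34, 1.10, 0.00, 0.16))
  expect_equal(summarize_ssr(all_loci[1, ], 1)$perfect_freq_pct[["1"]], 100)
  expect_error(summarize_ssr(all_loci, 0), ">= 1")
})
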