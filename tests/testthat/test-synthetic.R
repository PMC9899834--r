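test_that("generators are deterministic under a fixed seed", {
  s1 <- make_pedigree(pedigree_spec(mechanism = "terminal_fusion", y = 0.3,
                                    generations = 1, brood_sizes = 30,
                                    seed = 5))
  s2 <- make_pedigree(pedigree_spec(mechanism = "terminal_fusion", y = 0.3,
                                    generations = 1, brood_sizes = 30,
                                    seed = 5))
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))

  sp <- fasta_plant_spec(perfect_by_motif_length = c(1, 2, 1, 0, 0, 0),
                         n_compound = 1, n_imperfect = 1, seed = 6)
  f1 <- make_fasta(sp, tempfile(fileext = ".fa"))
  f2 <- make_fasta(sp, tempfile(fileext = ".fa"))
  expect_identical(readLines(f1$path), readLines(f2$path))
  expect_identical(f1$truth, f2$truth)
})

test_that("the default pedigree spec emulates the clonal laboratory design", {
  ped <- make_pedigree(pedigree_spec(seed = 9))
  tab <- ped$table
  expect_equal(nrow(tab), 8L + 96L + 63L + 60L)
  expect_equal(ped$truth$mechanism, "apomixis")
  genos <- unique(apply(as.data.frame(tab)[gt_loci(tab)], 1, paste,
                        collapse = ";"))
  expect_equal(length(genos), 1L)
})

test_that("pedigree truth round-trips through the inference stage", {
  # central fusion at y = 0.6: homozygote fraction should be near y/2 = 0.3
  big <- make_pedigree(pedigree_spec(mechanism = "central_fusion", y = 0.6,
                                     generations = 1, brood_sizes = 10000,
                                     n_founders = 1, seed = 13))
  s <- transition_summary(big$table, "DWTH119")
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(s$R - 0.3), 4 * se)
})

test_that("planted FASTA truth is recovered exactly by both scanners", {
  sp <- fasta_plant_spec(perfect_by_motif_length = c(3, 4, 3, 1, 1, 1),
                         n_compound = 3, n_imperfect = 3, seed = 21)
  f <- make_fasta(sp, tempfile(fileext = ".fa"))
  res <- scan_fasta(f$path, sp$config)
  expect_equal(nrow(res$loci), nrow(f$truth))
  expect_equal(res$loci$contig, f$truth$contig)
  expect_equal(res$loci$start, f$truth$start)
  expect_equal(res$loci$end, f$truth$end)
  expect_equal(res$loci$category, f$truth$category)
  nonc <- f$truth$category != "compound"
  expect_equal(res$loci$motif[nonc], f$truth$motif[nonc])
  expect_equal(res$loci$repeat_count[nonc], f$truth$repeat_count[nonc])
  # brute-force cross-check on every planted contig
  seqs <- Biostrings::readDNAStringSet(f$path)
  for (i in seq_along(seqs)) {
    expect_identical(scan_sequence(as.character(seqs[[i]]), sp$config),
                     scan_sequence_naive(as.character(seqs[[i]]), sp$config))
  }
})

test_that("a zero-plant spec yields a repeat-free FASTA", {
  sp <- fasta_plant_spec(perfect_by_motif_length = rep(0L, 6),
                         n_compound = 0, n_imperfect = 0, seed = 2)
  f <- make_fasta(sp, tempfile(fileext = ".fa"))
  expect_equal(nrow(f$truth), 0L)
  res <- scan_fasta(f$path)
  expect_equal(nrow(res$loci), 0L)
  expect_equal(res$n_contigs_with_ssr, 0L)
})

test_that("a single planted TG x 12 locus is recovered verbatim", {
  sp <- fasta_plant_spec(perfect_by_motif_length = c(0, 1, 0, 0, 0, 0),
                         n_compound = 0, n_imperfect = 0, seed = 33)
  # force the motif by rebuilding until TG x 12 appears is wasteful; instead
  # plant explicitly and scan
  s <- paste0("GGCATCAGCATTACGGACTA", strrep("TG", 12), "CATTACGCAGGACATCAGCA")
  hit <- scan_sequence(s)
  expect_equal(hit$motif, "TG")
  expect_equal(hit$repeat_count, 12L)
  # and the generator's own di plants carry a consistent truth record
  f <- make_fasta(sp, tempfile(fileext = ".fa"))
  expect_equal(f$truth$motif_length, 2L)
  hit2 <- scan_fasta(f$path)$loci
  expect_equal(hit2$motif, f$truth$motif)
  expect_equal(hit2$repeat_count, f$truth$repeat_count)
})

test_that("karyotype generator validates targets", {
  bad <- karyotype_targets()
  bad$CI_mean[1] <- 60
  expect_error(make_karyotype_measurements(bad), "CI")
  bad2 <- karyotype_targets()
  bad2$RL_mean <- bad2$RL_mean * 2
  expect_error(make_karyotype_measurements(bad2), "sum")
})
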