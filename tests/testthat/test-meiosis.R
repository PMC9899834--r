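test_that("meiosis separates or duplicates alleles according to y", {
  mother <- multilocus_genotype(list(L = c("a", "b")))
  # y = 0: first-division separation, one pole per allele
  p0 <- simulate_meiosis(mother, 0, seed = 1)
  expect_equal(length(unique(p0$products["L", 1:2])), 1L)
  expect_equal(length(unique(p0$products["L", 3:4])), 1L)
  expect_false(p0$products["L", 1] == p0$products["L", 3])
  # y = 1 (permissive): forced second-division segregation, both poles ab
  p1 <- simulate_meiosis(mother, 1, seed = 1, permissive = TRUE)
  expect_setequal(p1$products["L", 1:2], c("a", "b"))
  expect_setequal(p1$products["L", 3:4], c("a", "b"))
  # homozygous locus: all four products identical
  hom <- multilocus_genotype(list(L = c("a", "a")))
  ph <- simulate_meiosis(hom, 0.5, seed = 2)
  expect_true(all(ph$products["L", ] == "a"))
})

test_that("allele copies are conserved across the four products", {
  mother <- het_founder()
  for (seed in 1:25) {
    pr <- simulate_meiosis(mother, stats::setNames(c(0, 0.25, 0.5, 2 / 3),
                                                   names(mother)),
                           seed = seed)
    for (l in names(mother)) {
      expect_equal(sort(pr$products[l, ]),
                   sort(rep(mother[[l]], 2)))
    }
  }
})

test_that("meiosis rejects mismatched models and out-of-range y", {
  mother <- multilocus_genotype(list(L = c("a", "b")))
  expect_error(simulate_meiosis(mother, c(XX = 0.1)), "each locus")
  expect_error(simulate_meiosis(mother, 0.9), "2/3")
  expect_error(simulate_meiosis(mother, -0.1), "must lie")
})

test_that("diploidy restoration matches each mechanism's genetics at y = 0", {
  mother <- multilocus_genotype(list(L = c("a", "b")))
  for (seed in 1:40) {
    pr <- simulate_meiosis(mother, 0, seed = seed)
    gd <- restore_diploidy(pr, "gamete_duplication", seed = seed)
    expect_false(is_heterozygous(gd, "L"))  # aa or bb, never ab
    tf <- restore_diploidy(pr, "terminal_fusion", seed = seed)
    expect_false(is_heterozygous(tf, "L"))  # sisters identical without SDS
    cf <- restore_diploidy(pr, "central_fusion", seed = seed)
    expect_true(is_heterozygous(cf, "L"))   # poles carry opposite alleles
  }
})

test_that("apomixis is rejected by restore_diploidy and gives clones", {
  mother <- het_founder()
  pr <- simulate_meiosis(mother, 0, seed = 1)
  expect_error(restore_diploidy(pr, "apomixis"), "apomictic_offspring")
  off <- apomictic_offspring(mother)
  expect_identical(unclass(off), unclass(mother))
  son <- multilocus_genotype(list(L = "a"), ploidy = 1)
  expect_error(apomictic_offspring(son), "diploid")
})

test_that("closed-form rates reproduce the published values and ranges", {
  expect_equal(expected_homozygosity("apomixis", 0.5), 0)
  expect_equal(expected_homozygosity("gamete_duplication", 0.25), 1)
  expect_equal(expected_homozygosity("random_fusion", 0.4), 1 / 3)
  expect_equal(expected_homozygosity("central_fusion", 0.5), 0.25)
  # range endpoints: central fusion spans [0, 1/3], terminal [1/3, 1]
  expect_equal(expected_homozygosity("central_fusion", 0), 0)
  expect_equal(expected_homozygosity("central_fusion", 2 / 3), 1 / 3)
  expect_equal(expected_homozygosity("terminal_fusion", 0), 1)
  expect_equal(expected_homozygosity("terminal_fusion", 2 / 3), 1 / 3)
  expect_error(expected_homozygosity("central_fusion", 0.8), "2/3")
})

test_that("closed forms agree with chromatid-level enumeration to machine precision", {
  for (m in all_mechanisms) {
    for (y in y_grid) {
      expect_equal(expected_homozygosity(m, y), enumerate_homozygosity(m, y),
                   tolerance = 1e-14)
    }
  }
})

test_that("Monte-Carlo homozygosity is consistent with the closed forms", {
  n <- 20000
  for (m in all_mechanisms) {
    for (y in c(0, 0.5)) {
      mc <- mc_homozygosity(m, y, n, seed = 11)
      expected <- expected_homozygosity(m, y)
      tol <- 4 * max(mc$se, sqrt(expected * (1 - expected) / n))
      expect_lt(abs(mc$estimate - expected), max(tol, 1e-12))
    }
  }
  # degenerate mechanisms are exact, not just close
  expect_identical(mc_homozygosity("gamete_duplication", 0.5, 5000, 3)$estimate, 1)
  expect_identical(mc_homozygosity("apomixis", 0.5, 5000, 3)$estimate, 0)
})

test_that("the vectorised offspring sampler matches the explicit chromatid route", {
  # same distribution: compare homozygote fractions at moderate n
  mother <- multilocus_genotype(list(L = c("a", "b")))
  for (m in c("terminal_fusion", "central_fusion", "random_fusion")) {
    y <- 0.5
    set.seed(99)
    slow <- mean(vapply(1:2000, function(i) {
      pr <- simulate_meiosis(mother, y)
      !is_heterozygous(restore_diploidy(pr, m), "L")
    }, logical(1)))
    fast <- mc_homozygosity(m, y, 20000, seed = 100)$estimate
    se <- sqrt(0.25 / 2000) + sqrt(0.25 / 20000)
    expect_lt(abs(slow - fast), 4 * se)
  }
})

test_that("pedigrees are deterministic under a fixed seed and clonal under apomixis", {
  f <- het_founder()
  t1 <- simulate_pedigree(f, "central_fusion", 2, c(30, 20), models = 0.3,
                          seed = 42)
  t2 <- simulate_pedigree(f, "central_fusion", 2, c(30, 20), models = 0.3,
                          seed = 42)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  ap <- simulate_pedigree(f, "apomixis", 3, c(10, 10, 10), seed = 7)
  genos <- apply(as.data.frame(ap)[gt_loci(ap)], 1, paste, collapse = ";")
  expect_equal(length(unique(genos)), 1L)  # one multilocus genotype
})

test_that("pedigree mechanisms show their expected genetics", {
  f <- het_founder()
  gd <- simulate_pedigree(f, "gamete_duplication", 1, 50, seed = 5)
  off <- gd[gd$generation == "F1", ]
  for (l in gt_loci(gd)) {
    al <- strsplit(off[[l]], "/", fixed = TRUE)
    expect_true(all(vapply(al, function(p) p[1] == p[2], logical(1))))
  }
  # central fusion with y = 0 keeps every offspring heterozygous
  cf <- simulate_pedigree(f, "central_fusion", 2, c(40, 40), models = 0,
                          seed = 6)
  s <- transition_summary(cf, "L1")
  expect_equal(s$No, 0L)
})

test_that("arrhenotokous sons carry one maternal allele each, about 1:1", {
  f <- multilocus_genotype(list(L = c("a", "b")))
  sons <- arrhenotokous_sons(f, 400, seed = 8)
  alleles <- vapply(sons, function(s) s$L, character(1))
  expect_true(all(alleles %in% c("a", "b")))
  expect_gt(min(table(alleles)) / 400, 0.4)
})
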