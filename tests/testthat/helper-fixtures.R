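# Shared fixtures built in code.

het_founder <- function() {
  multilocus_genotype(list(
    L1 = c("a", "b"), L2 = c("101", "103"),
    L3 = c("7", "9"), L4 = c("x", "y")
  ))
}

toy_table <- function() {
  genotype_table(data.frame(
    id = c("m1", "o1", "o2", "o3"),
    generation = c("P", "F1", "F1", "F1"),
    mother_id = c(".", "m1", "m1", "m1"),
    sex = "F",
    L1 = c("a/b", "a/b", "b/a", "a/a"),
    stringsAsFactors = FALSE
  ))
}

all_mechanisms <- c("apomixis", "gamete_duplication", "terminal_fusion",
                    "central_fusion", "random_fusion")

y_grid <- c(0, 1 / 4, 1 / 2, 2 / 3)

locus_summaries <- function(tab) {
  do.call(rbind, lapply(gt_loci(tab), function(l) transition_summary(tab, l)))
}

fixture_path <- function() {
  system.file("extdata", "clonal_line_genotypes.tsv", package = "thelytools")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
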