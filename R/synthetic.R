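#' Founder genotype of the clonal laboratory line
#'
#' The four heterozygous marker loci (fragment-size alleles) carried by the
#' thelytokous laboratory line used throughout the worked examples:
#' DWTH119 169/171, DWTH366 145/147, DWTH178 191/197, DWTH340 160/168.
#'
#' @return A diploid [multilocus_genotype()].
#' @export
clonal_line_founder <- function() {
  multilocus_genotype(list(
    DWTH119 = c("169", "171"),
    DWTH366 = c("145", "147"),
    DWTH178 = c("191", "197"),
    DWTH340 = c("160", "168")
  ))
}

#' Pedigree specification
#'
#' Bundles everything [make_pedigree()] needs. The defaults emulate the
#' clonal laboratory design: 8 founder females of one heterozygous
#' four-locus genotype followed by three generations of brood sizes 96, 63
#' and 60.
#'
#' @param founder Founder [multilocus_genotype()].
#' @param mechanism Diploidy-restoration mechanism (including
#'   `"apomixis"`).
#' @param y Second-division segregation probability per locus (named
#'   vector) or a single number.
#' @param generations,brood_sizes Pedigree depth and per-generation brood
#'   sizes.
#' @param n_founders Number of identical founder females.
#' @param seed Integer seed.
#' @return List of class `pedigree_spec`.
#' @export
pedigree_spec <- function(founder = clonal_line_founder(),
                          mechanism = "apomixis", y = 0,
                          generations = 3L, brood_sizes = c(96L, 63L, 60L),
                          n_founders = 8L, seed = 1L) {
  check_mechanism(mechanism)
  if (length(brood_sizes) != generations) {
    stop_validation("need one brood size per generation")
  }
  structure(
    list(founder = founder, mechanism = mechanism, y = y,
         generations = as.integer(generations),
         brood_sizes = as.integer(brood_sizes),
         n_founders = as.integer(n_founders), seed = check_seed(seed)),
    class = "pedigree_spec"
  )
}

#' Generate a pedigree genotype table with known truth
#'
#' @param spec A [pedigree_spec()].
#' @return List with `table` (a [genotype_table()]) and `truth`
#'   (mechanism and `y` used), for parameter-recovery tests.
#' @export
make_pedigree <- function(spec = pedigree_spec()) {
  stopifnot(inherits(spec, "pedigree_spec"))
  tab <- simulate_pedigree(
    spec$founder, spec$mechanism, spec$generations, spec$brood_sizes,
    models = spec$y, seed = spec$seed, n_founders = spec$n_founders
  )
  list(table = tab, truth = list(mechanism = spec$mechanism, y = spec$y))
}

# --- FASTA planting ---------------------------------------------------------

random_bases <- function(n, gc = 0.4) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

random_primitive_motif <- function(k, gc = 0.4) {
  repeat {
    u <- paste(random_bases(k, gc), collapse = "")
    if (is_primitive_motif(u)) return(u)
  }
}

#' FASTA planting specification
#'
#' Describes a synthetic contig set with planted SSR loci of known
#' position, motif, count and category. The defaults emulate the microsatellite
#' composition recovered from the thelytokous genomic library: 636 contigs
#' with one SSR each — 563 perfect (124 mono-, 308 di-, 123 tri-, 7 tetra-,
#' 0 penta-, 1 hexanucleotide), 59 compound, and 14 imperfect.
#'
#' @param perfect_by_motif_length Integer vector of length 6: planted
#'   perfect loci per motif length 1..6.
#' @param n_compound,n_imperfect Planted compound / imperfect contigs.
#' @param flank_bp Repeat-free flank length on each side of a planted
#'   locus.
#' @param gc GC fraction of background sequence.
#' @param config [scan_config()] the planting must be consistent with.
#' @param seed Integer seed.
#' @return List of class `fasta_plant_spec`.
#' @export
fasta_plant_spec <- function(perfect_by_motif_length = c(124L, 308L, 123L, 7L, 0L, 1L),
                             n_compound = 59L, n_imperfect = 14L,
                             flank_bp = 60L, gc = 0.4,
                             config = scan_config(), seed = 1L) {
  if (length(perfect_by_motif_length) != 6L ||
      any(perfect_by_motif_length < 0) || n_compound < 0 || n_imperfect < 0) {
    stop_validation("planted counts must be non-negative (6 perfect classes)")
  }
  if (flank_bp < 20L) stop_validation("flanks shorter than 20 bp cannot be kept repeat-free reliably")
  structure(
    list(perfect_by_motif_length = as.integer(perfect_by_motif_length),
         n_compound = as.integer(n_compound),
         n_imperfect = as.integer(n_imperfect),
         flank_bp = as.integer(flank_bp), gc = gc, config = config,
         seed = check_seed(seed)),
    class = "fasta_plant_spec"
  )
}

# Build one contig with a single planted locus; re-draw flanks until the
# scanner recovers exactly the planted truth (the scanner is the oracle for
# repeat-free background; a brute-force scanner cross-checks it in tests).
plant_contig <- function(insert, truth_row, spec, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    left <- paste(random_bases(spec$flank_bp, spec$gc), collapse = "")
    right <- paste(random_bases(spec$flank_bp, spec$gc), collapse = "")
    contig <- paste0(left, insert, right)
    found <- scan_sequence(contig, spec$config)
    ok <- nrow(found) == 1L &&
      found$start == spec$flank_bp &&
      found$end == spec$flank_bp + nchar(insert) &&
      found$category == truth_row$category &&
      (is.na(truth_row$repeat_count) ||
         found$repeat_count == truth_row$repeat_count) &&
      (truth_row$category == "compound" || found$motif == truth_row$motif)
    if (ok) return(contig)
  }
  stop_validation("could not plant locus in a repeat-free context (infeasible packing)")
}

#' Generate a FASTA file with planted SSR loci
#'
#' Writes one contig per planted locus, each a repeat-free background with
#' a single perfect, imperfect, or compound microsatellite of known truth.
#' Background flanks are rejection-sampled against the scanner itself so
#' that the only detectable locus is the planted one.
#'
#' @param spec A [fasta_plant_spec()].
#' @param path Output FASTA path.
#' @return List with `path` and `truth` (data.frame: contig, start, end,
#'   motif, motif_length, repeat_count, category).
#' @export
make_fasta <- function(spec = fasta_plant_spec(), path = tempfile(fileext = ".fasta")) {
  stopifnot(inherits(spec, "fasta_plant_spec"))
  set.seed(spec$seed)
  cfg <- spec$config
  plan <- list()
  for (k in 1:6) {
    nk <- spec$perfect_by_motif_length[k]
    if (nk > 0L) {
      plan <- c(plan, replicate(nk, list(type = "perfect", k = k),
                                simplify = FALSE))
    }
  }
  plan <- c(
    plan,
    replicate(spec$n_imperfect, list(type = "imperfect"), simplify = FALSE),
    replicate(spec$n_compound, list(type = "compound"), simplify = FALSE)
  )
  if (length(plan) == 0L) {
    repeat {
      bg <- paste(random_bases(2L * spec$flank_bp, spec$gc), collapse = "")
      if (nrow(scan_sequence(bg, cfg)) == 0L) break
    }
    writeLines(c(">contig0001", bg), path)
    return(list(path = path, truth = ssr_empty()))
  }

  contigs <- character(length(plan))
  truth <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    id <- sprintf("contig%04d", i)
    ok <- FALSE
    for (try in seq_len(200L)) {
      built <- build_insert(p, id, spec)
      sc <- scan_sequence(built$insert, cfg)
      ok <- nrow(sc) == 1L && sc$start == 0L &&
        sc$end == nchar(built$insert) &&
        sc$category == built$truth$category &&
        (is.na(built$truth$repeat_count) ||
           sc$repeat_count == built$truth$repeat_count) &&
        (built$truth$category == "compound" ||
           sc$motif == built$truth$motif)
      if (ok) break
    }
    if (!ok) stop_validation("could not build a planted insert (infeasible packing)")
    contigs[i] <- plant_contig(built$insert, built$truth, spec)
    truth[[i]] <- built$truth
  }
  lines <- character(2L * length(plan))
  lines[seq(1L, by = 2L, length.out = length(plan))] <-
    paste0(">", sprintf("contig%04d", seq_along(plan)))
  lines[seq(2L, by = 2L, length.out = length(plan))] <- contigs
  writeLines(lines, path)
  list(path = path, truth = do.call(rbind, truth))
}

# One planted insert plus its truth row; inserts whose interruption or
# spacer characters perturb the repeat structure are re-drawn by the caller.
build_insert <- function(p, id, spec) {
  cfg <- spec$config
  if (p$type == "perfect") {
    k <- p$k
    unit <- random_primitive_motif(k, spec$gc)
    count <- cfg$min_repeats[k] + sample(0:3, 1L)
    insert <- paste(rep(unit, count), collapse = "")
    tr <- data.frame(contig = id, start = spec$flank_bp,
                     end = spec$flank_bp + nchar(insert), motif = unit,
                     motif_length = k, repeat_count = count,
                     category = "perfect", stringsAsFactors = FALSE)
  } else if (p$type == "imperfect") {
    k <- sample(1:3, 1L)
    unit <- random_primitive_motif(k, spec$gc)
    total <- cfg$min_repeats[k] + sample(1:3, 1L)
    c1 <- sample(2:(total - 2L), 1L)
    c2 <- total - c1
    gap <- sample(seq_len(cfg$max_interruption_bp), 1L)
    interruption <- paste(random_bases(gap, spec$gc), collapse = "")
    insert <- paste0(paste(rep(unit, c1), collapse = ""), interruption,
                     paste(rep(unit, c2), collapse = ""))
    tr <- data.frame(contig = id, start = spec$flank_bp,
                     end = spec$flank_bp + nchar(insert), motif = unit,
                     motif_length = k, repeat_count = total,
                     category = "imperfect", stringsAsFactors = FALSE)
  } else {
    ks <- sample(1:3, 2L, replace = FALSE)
    u1 <- random_primitive_motif(ks[1], spec$gc)
    u2 <- random_primitive_motif(ks[2], spec$gc)
    n1 <- cfg$min_repeats[ks[1]] + sample(0:2, 1L)
    n2 <- cfg$min_repeats[ks[2]] + sample(0:2, 1L)
    gap <- cfg$max_interruption_bp + sample(2:6, 1L)
    spacer <- paste(random_bases(gap, spec$gc), collapse = "")
    insert <- paste0(paste(rep(u1, n1), collapse = ""), spacer,
                     paste(rep(u2, n2), collapse = ""))
    tr <- data.frame(contig = id, start = spec$flank_bp,
                     end = spec$flank_bp + nchar(insert),
                     motif = NA_character_, motif_length = NA_integer_,
                     repeat_count = NA_integer_, category = "compound",
                     stringsAsFactors = FALSE)
  }
  list(insert = insert, truth = tr)
}

# --- karyotype measurements -------------------------------------------------

#' Published karyotype targets
#'
#' Per-pair mean and standard deviation of relative length (RL) and
#' centromeric index (CI) for the two strains (five chromosome pairs each);
#' used as targets for [make_karyotype_measurements()] and as inputs to the
#' karyotype stage.
#'
#' @param strain `"thelytokous"` or `"arrhenotokous"`.
#' @return data.frame: `pair_id`, `RL_mean`, `RL_sd`, `CI_mean`, `CI_sd`.
#' @export
karyotype_targets <- function(strain = c("thelytokous", "arrhenotokous")) {
  strain <- match.arg(strain)
  if (strain == "thelytokous") {
    data.frame(
      pair_id = 1:5,
      RL_mean = c(27.00, 21.74, 20.41, 18.46, 12.38),
      RL_sd = c(1.34, 1.10, 0.49, 1.08, 0.99),
      CI_mean = c(46.54, 47.06, 34.76, 45.76, 43.05),
      CI_sd = c(2.31, 2.00, 2.14, 2.06, 2.13)
    )
  } else {
    data.frame(
      pair_id = 1:5,
      RL_mean = c(25.38, 21.55, 20.14, 19.30, 13.63),
      RL_sd = c(1.47, 0.71, 0.73, 0.72, 0.94),
      CI_mean = c(46.96, 47.29, 35.42, 45.82, 45.41),
      CI_sd = c(1.95, 1.32, 1.27, 2.47, 3.45)
    )
  }
}

#' Generate chromosome arm measurements around targets
#'
#' Draws per-cell chromosome total lengths and centromeric indices from
#' Gaussian jitter around the target means and converts them to short/long
#' arm pairs. With zero standard deviations the targets are recovered
#' exactly.
#'
#' @param targets data.frame as from [karyotype_targets()].
#' @param n_cells Number of cells (replicates).
#' @param seed Integer seed.
#' @return List with `measurements` (data.frame: pair_id, replicate,
#'   short_arm, long_arm) and `truth` (the targets).
#' @export
make_karyotype_measurements <- function(targets = karyotype_targets(),
                                        n_cells = 15L, seed = 1L) {
  need <- c("pair_id", "RL_mean", "RL_sd", "CI_mean", "CI_sd")
  if (!all(need %in% names(targets))) {
    stop_validation(sprintf("targets need columns: %s",
                            paste(need, collapse = ", ")))
  }
  if (any(targets$CI_mean <= 0) || any(targets$CI_mean > 50)) {
    stop_validation("target CI means must lie in (0, 50]")
  }
  if (abs(sum(targets$RL_mean) - 100) > 1) {
    stop_validation("target RL means must sum to ~100")
  }
  set.seed(check_seed(seed))
  rows <- list()
  for (cell in seq_len(n_cells)) {
    total <- stats::rnorm(nrow(targets), targets$RL_mean, targets$RL_sd)
    total <- pmax(total, 0.1)
    ci <- stats::rnorm(nrow(targets), targets$CI_mean, targets$CI_sd)
    ci <- pmin(pmax(ci, 1), 50)
    short <- total * ci / 100
    rows[[cell]] <- data.frame(
      pair_id = targets$pair_id,
      replicate = sprintf("cell%02d", cell),
      short_arm = short, long_arm = total - short
    )
  }
  list(measurements = do.call(rbind, rows), truth = targets)
}
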