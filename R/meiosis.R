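#' Chromatid-level simulation of one meiosis
#'
#' Simulates the four haploid products of a single meiosis in a diploid
#' mother. Each locus segregates independently: with probability `y` (the
#' per-meiosis probability of second-division segregation, caused by a
#' crossover between centromere and locus) both first-division poles carry
#' one copy of each maternal allele; otherwise the two maternal alleles are
#' separated at the first division and each pole's two sister chromatids
#' carry the same allele.
#'
#' Products 1 and 2 come from first-division pole 1, products 3 and 4 from
#' pole 2; products (1,2) and (3,4) are sister pairs sharing a
#' second-division spindle. The egg pronucleus is chosen uniformly among the
#' four products; the other three are prospective polar bodies.
#'
#' @param mother A diploid [multilocus_genotype()].
#' @param models Named numeric vector giving `y` per locus (names must match
#'   the mother's loci), or a single number recycled to all loci.
#' @param seed Optional integer seed for reproducibility.
#' @param permissive Allow `y` up to 1 (unit-test mode); the biological
#'   domain is `[0, 2/3]`.
#' @return A `meiosis_products` object: `products` (loci x 4 character
#'   matrix of allele labels), `pole` (c(1,1,2,2)), `sister_pairs`, and
#'   `egg_index`.
#' @export
simulate_meiosis <- function(mother, models, seed = NULL, permissive = FALSE) {
  stopifnot(inherits(mother, "multilocus_genotype"))
  if (attr(mother, "ploidy") != 2L) {
    stop_validation("meiosis is simulated for diploid mothers only")
  }
  y <- resolve_locus_models(models, names(mother), permissive)
  if (!is.null(seed)) set.seed(check_seed(seed))

  nl <- length(mother)
  prods <- matrix("", nrow = nl, ncol = 4,
                  dimnames = list(names(mother), NULL))
  for (i in seq_len(nl)) {
    al <- mother[[i]]
    if (stats::runif(1) < y[i]) {
      # second-division segregation: both poles carry both alleles,
      # sister chromatids on one spindle differ
      prods[i, ] <- c(al[1], al[2], al[1], al[2])
    } else {
      # first-division separation: whole pole carries one allele
      first <- sample(al, 1)
      other <- if (first == al[1]) al[2] else al[1]
      prods[i, ] <- c(first, first, other, other)
    }
  }
  structure(
    list(
      products = prods,
      pole = c(1L, 1L, 2L, 2L),
      sister_pairs = list(c(1L, 2L), c(3L, 4L)),
      egg_index = sample.int(4L, 1L)
    ),
    class = "meiosis_products"
  )
}

resolve_locus_models <- function(models, loci, permissive = FALSE) {
  if (is.numeric(models) && length(models) == 1L && is.null(names(models))) {
    y <- rep(models, length(loci))
    names(y) <- loci
  } else {
    y <- unlist(models)
    if (is.null(names(y)) || !setequal(names(y), loci)) {
      stop_validation(
        "models must name a second-division segregation probability for each locus"
      )
    }
    y <- y[loci]
  }
  check_y(y, permissive = permissive)
  y
}

#' Restore diploidy from meiotic products
#'
#' Applies one of the four automictic diploidy-restoration mechanisms to the
#' products of [simulate_meiosis()]:
#' \describe{
#'   \item{gamete_duplication}{the egg pronucleus is doubled; the offspring
#'     is homozygous at every locus.}
#'   \item{terminal_fusion}{the egg fuses with its sister product (same
#'     second-division spindle).}
#'   \item{central_fusion}{the egg fuses with a product of the opposite
#'     first-division pole, chosen uniformly.}
#'   \item{random_fusion}{two distinct products are chosen uniformly among
#'     the four, without regard to pedigree.}
#' }
#' Fusion is a cell-level event: the same pair of nuclei supplies the
#' alleles at every locus.
#'
#' @param prod A `meiosis_products` object.
#' @param mech One of `"gamete_duplication"`, `"terminal_fusion"`,
#'   `"central_fusion"`, `"random_fusion"`. Apomixis bypasses meiosis; use
#'   [apomictic_offspring()] instead.
#' @param seed Optional integer seed.
#' @return A diploid [multilocus_genotype()].
#' @export
restore_diploidy <- function(prod, mech, seed = NULL) {
  stopifnot(inherits(prod, "meiosis_products"))
  check_mechanism(mech)
  if (mech == "apomixis") {
    stop_validation(
      "apomixis does not restore diploidy from meiotic products; use apomictic_offspring()"
    )
  }
  if (!is.null(seed)) set.seed(check_seed(seed))
  e <- prod$egg_index
  sister <- c(2L, 1L, 4L, 3L)
  pair <- switch(
    mech,
    gamete_duplication = c(e, e),
    terminal_fusion = c(e, sister[e]),
    central_fusion = c(e, sample(if (e <= 2L) 3L:4L else 1L:2L, 1L)),
    random_fusion = sample.int(4L, 2L)
  )
  loci <- rownames(prod$products)
  geno <- lapply(seq_along(loci), function(i) prod$products[i, pair])
  names(geno) <- loci
  multilocus_genotype(geno, ploidy = 2L)
}

#' Clonal (apomictic) offspring
#'
#' Under apomixis meiosis is absent and the diploid offspring is a genetic
#' clone of its mother: identical genotype at every locus, no randomness.
#'
#' @param mother A diploid [multilocus_genotype()].
#' @return The offspring genotype, identical to `mother`.
#' @export
apomictic_offspring <- function(mother) {
  stopifnot(inherits(mother, "multilocus_genotype"))
  if (attr(mother, "ploidy") != 2L) {
    stop_validation("apomictic offspring require a diploid mother")
  }
  mother
}

#' Expected rate of transition to homozygosity
#'
#' Closed-form expected rate `r` at which a heterozygous maternal locus
#' becomes homozygous in offspring, per mechanism:
#' apomixis 0; gamete duplication 1; random fusion 1/3 (independent of
#' recombination); central fusion `y/2`; terminal fusion `1 - y`, where `y`
#' is the probability of second-division segregation at the locus. Over the
#' biological domain `y` in `[0, 2/3]` central fusion spans `[0, 1/3]` and
#' terminal fusion `[1/3, 1]`.
#'
#' @param mech Mechanism name.
#' @param y Second-division segregation probability, in `[0, 2/3]`
#'   (vectorised).
#' @param permissive Allow `y` up to 1.
#' @return Expected homozygosity rate(s) in `[0, 1]`.
#' @seealso [enumerate_homozygosity()] for the exhaustive chromatid-level
#'   enumeration these forms are validated against.
#' @export
expected_homozygosity <- function(mech, y = 0, permissive = FALSE) {
  check_mechanism(mech)
  check_y(y, permissive = permissive)
  switch(
    mech,
    apomixis = rep(0, length(y)) + 0 * y,
    gamete_duplication = rep(1, length(y)) + 0 * y,
    random_fusion = rep(1 / 3, length(y)) + 0 * y,
    central_fusion = y / 2,
    terminal_fusion = 1 - y
  )
}

#' Exhaustive enumeration oracle for the homozygosity rate
#'
#' Computes the probability that an offspring of an `ab` heterozygous mother
#' is homozygous at the locus by enumerating, with exact weights, the two
#' segregation states (first-division separation with weight `1 - y`,
#' second-division segregation with weight `y`), every choice of egg
#' pronucleus, and every admissible fusion for the mechanism. This is an
#' independent check on [expected_homozygosity()]; it shares no code with
#' the closed forms or the simulator.
#'
#' @inheritParams expected_homozygosity
#' @return Exact homozygosity probability.
#' @export
enumerate_homozygosity <- function(mech, y = 0, permissive = FALSE) {
  check_mechanism(mech)
  check_y(y, permissive = permissive)
  if (length(y) > 1L) {
    return(vapply(y, function(yy) enumerate_homozygosity(mech, yy, permissive),
                  numeric(1)))
  }
  if (mech == "apomixis") return(0)

  # chromatid layouts: columns are the 4 products; rows index segregation
  # state. Pole of product j is c(1,1,2,2)[j]; sister of j is c(2,1,4,3)[j].
  layouts <- list(
    list(w = 1 - y, alleles = c("a", "a", "b", "b")),  # first-division separation
    list(w = y,     alleles = c("a", "b", "a", "b"))   # second-division segregation
  )
  sister <- c(2L, 1L, 4L, 3L)
  p_hom <- 0
  for (lay in layouts) {
    if (lay$w == 0) next
    al <- lay$alleles
    if (mech == "random_fusion") {
      pairs <- utils::combn(4L, 2L)
      hom <- mean(al[pairs[1, ]] == al[pairs[2, ]])
      p_hom <- p_hom + lay$w * hom
    } else {
      for (egg in 1L:4L) {
        partners <- switch(
          mech,
          gamete_duplication = egg,
          terminal_fusion = sister[egg],
          central_fusion = if (egg <= 2L) 3L:4L else 1L:2L
        )
        hom <- mean(al[egg] == al[partners])
        p_hom <- p_hom + lay$w * hom / 4
      }
    }
  }
  p_hom
}

# Vectorised single-locus offspring sampler used by mc_homozygosity() and
# simulate_pedigree(). a, b: maternal allele labels (length 1 or n). Returns
# an n x 2 character matrix of offspring allele pairs. The chromatid logic
# mirrors simulate_meiosis()/restore_diploidy(); a unit test asserts the two
# routes agree.
sample_offspring_locus <- function(a, b, mech, y, n, permissive = FALSE) {
  check_mechanism(mech)
  check_y(y, permissive = permissive)
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (mech == "apomixis") return(cbind(a, b, deparse.level = 0))

  sds <- stats::runif(n) < y
  flip <- stats::runif(n) < 0.5
  first <- ifelse(flip, a, b)
  other <- ifelse(flip, b, a)
  # product allele matrix, columns = products 1..4
  P <- cbind(first, first, other, other, deparse.level = 0)
  if (any(sds)) P[sds, ] <- cbind(a, b, a, b, deparse.level = 0)[sds, ]

  e <- sample.int(4L, n, replace = TRUE)
  partner <- switch(
    mech,
    gamete_duplication = e,
    terminal_fusion = c(2L, 1L, 4L, 3L)[e],
    central_fusion = ifelse(e <= 2L, 3L, 1L) + (stats::runif(n) < 0.5),
    # uniform unordered pair of distinct products: egg uniform, partner
    # uniform among the remaining three
    random_fusion = ((e - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  )
  cbind(P[cbind(seq_len(n), e)], P[cbind(seq_len(n), partner)],
        deparse.level = 0)
}

#' Monte-Carlo estimate of the homozygosity rate
#'
#' Simulates `n_offspring` independent meioses plus diploidy restoration at
#' a single heterozygous locus and reports the fraction of homozygous
#' offspring with its binomial standard error. Cross-checks the closed forms
#' of [expected_homozygosity()].
#'
#' @inheritParams expected_homozygosity
#' @param n_offspring Number of simulated offspring (>= 1).
#' @param seed Integer seed; identical seeds give identical estimates.
#' @return A list with `estimate`, `se`, and `n`.
#' @export
mc_homozygosity <- function(mech, y = 0, n_offspring = 10000L, seed = 1L,
                            permissive = FALSE) {
  if (n_offspring < 1) stop_validation("n_offspring must be >= 1")
  set.seed(check_seed(seed))
  off <- sample_offspring_locus("a", "b", mech, y, n_offspring,
                                permissive = permissive)
  p <- mean(off[, 1] == off[, 2])
  list(estimate = p, se = sqrt(p * (1 - p) / n_offspring), n = n_offspring)
}

#' Haploid sons of an arrhenotokous mother
#'
#' Under arrhenotoky unfertilised eggs develop into haploid males; each son
#' carries one maternal allele per locus, chosen uniformly. Used to verify
#' that marker loci segregate (a heterozygous mother's sons show each allele
#' singly, at a ~1:1 ratio).
#'
#' @param mother A diploid [multilocus_genotype()].
#' @param n Number of sons.
#' @param seed Integer seed.
#' @return List of haploid `multilocus_genotype` objects.
#' @export
arrhenotokous_sons <- function(mother, n, seed = 1L) {
  stopifnot(inherits(mother, "multilocus_genotype"))
  if (attr(mother, "ploidy") != 2L) {
    stop_validation("sons are drawn from a diploid mother")
  }
  set.seed(check_seed(seed))
  lapply(seq_len(n), function(i) {
    geno <- lapply(mother, function(al) sample(al, 1L))
    multilocus_genotype(geno, ploidy = 1L)
  })
}

#' Simulate a multi-generation thelytokous pedigree
#'
#' Produces a genotype table of diploid female offspring over successive
#' generations under one diploidy-restoration mechanism. Each generation's
#' mothers are drawn uniformly from the previous generation's females; loci
#' segregate independently.
#'
#' @param mother Founder [multilocus_genotype()] (diploid).
#' @param mech Mechanism name (including `"apomixis"`).
#' @param generations Number of offspring generations (>= 1).
#' @param brood_sizes Integer vector, offspring count per generation.
#' @param models Named `y` per locus or a single number (ignored under
#'   apomixis).
#' @param seed Integer seed.
#' @param n_founders Number of identical founder females listed as parents
#'   (clonal laboratory lines start from several sisters of one genotype).
#' @return A [genotype_table()] with generation labels `"P"`, `"F1"`, ...
#'   and mother links.
#' @export
simulate_pedigree <- function(mother, mech, generations, brood_sizes,
                              models = 0, seed = 1L, n_founders = 1L,
                              permissive = FALSE) {
  stopifnot(inherits(mother, "multilocus_genotype"))
  check_mechanism(mech)
  if (generations < 1) stop_validation("generations must be >= 1")
  if (length(brood_sizes) != generations) {
    stop_validation("need one brood size per generation")
  }
  if (any(brood_sizes < 1)) stop_validation("brood sizes must be >= 1")
  loci <- names(mother)
  y <- if (mech == "apomixis") stats::setNames(rep(0, length(loci)), loci)
       else resolve_locus_models(models, loci, permissive)
  set.seed(check_seed(seed))

  founder_str <- vapply(mother, genotype_string, character(1))
  rows <- data.frame(
    id = sprintf("P%02d", seq_len(n_founders)),
    generation = "P",
    mother_id = ".",
    sex = "F",
    stringsAsFactors = FALSE
  )
  for (l in loci) rows[[l]] <- founder_str[[l]]

  prev <- rows
  for (g in seq_len(generations)) {
    n <- brood_sizes[g]
    if (nrow(prev) == 0L) {
      stop_validation(sprintf(
        "generation %d has no females to mother the next brood", g - 1L
      ))
    }
    midx <- sample.int(nrow(prev), n, replace = TRUE)
    gen <- data.frame(
      id = sprintf("F%d_%03d", g, seq_len(n)),
      generation = paste0("F", g),
      mother_id = prev$id[midx],
      sex = "F",
      stringsAsFactors = FALSE
    )
    for (l in loci) {
      mg <- strsplit(prev[[l]][midx], "/", fixed = TRUE)
      ma <- vapply(mg, `[`, character(1), 1L)
      mb <- vapply(mg, `[`, character(1), 2L)
      off <- sample_offspring_locus(ma, mb, mech, y[[l]], n,
                                    permissive = permissive)
      gen[[l]] <- paste(pmin(off[, 1], off[, 2]), pmax(off[, 1], off[, 2]),
                        sep = "/")
    }
    rows <- rbind(rows, gen)
    prev <- gen
  }
  genotype_table(rows, loci = loci)
}
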