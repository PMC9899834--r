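#' Construct a multilocus genotype
#'
#' A multilocus genotype stores, for each named locus, an unordered pair of
#' allele labels (fragment sizes such as `"169"`, or letters in toy
#' examples). Diploid females carry two alleles per locus; equality of
#' alleles is label equality.
#'
#' @param loci Named list; each element a character (or numeric) vector of
#'   2 allele labels for diploids, 1 for haploids.
#' @param ploidy Integer, 2 (female) or 1 (male).
#' @return An object of class `multilocus_genotype`: a named list of sorted
#'   character allele vectors with a `ploidy` attribute.
#' @examples
#' multilocus_genotype(list(DWTH119 = c("169", "171")))
#' @export
multilocus_genotype <- function(loci, ploidy = 2L) {
  if (!is.list(loci) || is.null(names(loci)) || any(names(loci) == "") ||
      anyDuplicated(names(loci))) {
    stop_validation("loci must be a uniquely named list of allele pairs")
  }
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) {
    stop_validation("ploidy must be 1 (haploid male) or 2 (diploid female)")
  }
  loci <- lapply(loci, function(a) {
    a <- as.character(a)
    if (length(a) != ploidy || any(is.na(a)) || any(!nzchar(a))) {
      stop_validation(sprintf(
        "each locus needs exactly %d non-empty allele label(s)", ploidy
      ))
    }
    sort(a)
  })
  structure(loci, ploidy = ploidy, class = "multilocus_genotype")
}

#' @export
print.multilocus_genotype <- function(x, ...) {
  cat(sprintf("<multilocus_genotype: ploidy %d>\n", attr(x, "ploidy")))
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = "/")))
  invisible(x)
}

#' Is a genotype heterozygous at a locus?
#'
#' @param geno A `multilocus_genotype`.
#' @param locus Locus name; if missing, returns a named logical over loci.
#' @return Logical; `NA` for haploid genotypes (zygosity undefined).
#' @export
is_heterozygous <- function(geno, locus = NULL) {
  stopifnot(inherits(geno, "multilocus_genotype"))
  f <- function(a) if (length(a) == 2L) a[1] != a[2] else NA
  if (is.null(locus)) return(vapply(geno, f, logical(1)))
  if (!locus %in% names(geno)) stop_validation(sprintf("unknown locus '%s'", locus))
  f(geno[[locus]])
}

genotype_string <- function(alleles) paste(sort(alleles), collapse = "/")
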