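#' Allele frequencies at a locus
#'
#' Counts allele copies across all typed individuals: diploids contribute
#' two gene copies, haploid males one. Missing calls (`"."`) are skipped.
#'
#' @param table A [genotype_table()].
#' @param locus Locus name.
#' @return List of class `allele_frequencies`: `locus`, `counts` (named
#'   integer vector), `n_gene_copies`, `n_diploid` (typed diploid
#'   individuals), `n_het_diploid` (heterozygous among them).
#' @export
allele_frequencies <- function(table, locus) {
  stopifnot(inherits(table, "genotype_table"))
  al <- gt_alleles(table, locus)
  typed <- !is.na(al[, 1])
  if (!any(typed)) {
    stop_validation(sprintf("locus %s is untyped in every individual", locus))
  }
  copies <- c(al[typed, 1], al[typed & !is.na(al[, 2]), 2])
  counts <- table(copies)
  counts <- stats::setNames(as.integer(counts), names(counts))
  diploid <- typed & !is.na(al[, 2])
  structure(
    list(
      locus = locus,
      counts = counts,
      n_gene_copies = sum(counts),
      n_diploid = sum(diploid),
      n_het_diploid = sum(diploid & al[, 1] != al[, 2], na.rm = TRUE)
    ),
    class = "allele_frequencies"
  )
}

#' Heterozygosity and polymorphic information content
#'
#' From allele frequencies `p_i` computes:
#' \describe{
#'   \item{HO}{observed heterozygosity, heterozygous diploids / typed
#'     diploids (haploids carry one allele and are excluded).}
#'   \item{HE}{expected heterozygosity; by default the small-sample
#'     unbiased estimator `C/(C-1) * (1 - sum p_i^2)` with `C` the number of
#'     gene copies, or the plain gene diversity `1 - sum p_i^2` with
#'     `unbiased = FALSE`.}
#'   \item{PIC}{polymorphic information content,
#'     `1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`.}
#' }
#'
#' @param freqs An [allele_frequencies()] object.
#' @param unbiased Apply the small-sample correction to HE (default TRUE).
#' @return Named numeric vector `c(HO, HE, PIC)`, each in `[0, 1]`.
#' @export
het_and_pic <- function(freqs, unbiased = TRUE) {
  stopifnot(inherits(freqs, "allele_frequencies"))
  if (freqs$n_diploid < 1) {
    stop_validation("observed heterozygosity needs at least one typed diploid")
  }
  p <- freqs$counts / freqs$n_gene_copies
  HO <- freqs$n_het_diploid / freqs$n_diploid
  D <- 1 - sum(p^2)
  C <- freqs$n_gene_copies
  HE <- if (unbiased && C > 1) C / (C - 1) * D else D
  HE <- min(HE, 1)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4
  p2 <- p^2
  PIC <- 1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
  c(HO = HO, HE = HE, PIC = max(PIC, 0))
}

#' Per-locus marker polymorphism report
#'
#' One row per locus with the number of alleles (`NA_` to avoid the R
#' missing-value clash), `HO`, `HE`, `PIC`, and a `highly_polymorphic` flag
#' (`PIC > 0.5`).
#'
#' @param table A [genotype_table()].
#' @param loci Locus names; default all loci in the table.
#' @param unbiased Passed to [het_and_pic()].
#' @return data.frame with columns `locus`, `NA_`, `HO`, `HE`, `PIC`,
#'   `highly_polymorphic`.
#' @export
polymorphism_report <- function(table, loci = gt_loci(table), unbiased = TRUE) {
  if (length(loci) == 0L) {
    return(data.frame(
      locus = character(), NA_ = integer(), HO = numeric(), HE = numeric(),
      PIC = numeric(), highly_polymorphic = logical()
    ))
  }
  do.call(rbind, lapply(loci, function(l) {
    fr <- allele_frequencies(table, l)
    hp <- het_and_pic(fr, unbiased = unbiased)
    data.frame(
      locus = l, NA_ = length(fr$counts),
      HO = hp[["HO"]], HE = hp[["HE"]], PIC = hp[["PIC"]],
      highly_polymorphic = hp[["PIC"]] > 0.5,
      stringsAsFactors = FALSE
    )
  }))
}
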