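#' Summarise transitions to homozygosity at a locus
#'
#' For every diploid offspring whose mother is heterozygous at the locus,
#' counts heterozygous (`Nt`) and homozygous (`No`) genotypes and forms the
#' observed transition rate `R = No / (Nt + No)`. Offspring of homozygous
#' mothers are uninformative for the transition rate; they are excluded and
#' reported in `n_excluded` (with a warning when present). Individuals with
#' no mother link (founders, field-collected individuals) are not counted.
#'
#' @param table A [genotype_table()].
#' @param locus Locus name.
#' @return A data.frame row of class `locus_segregation_summary`: `locus`,
#'   `Nt`, `No`, `R` (`NA` when no eligible offspring), `n_excluded`.
#' @export
transition_summary <- function(table, locus) {
  stopifnot(inherits(table, "genotype_table"))
  al <- gt_alleles(table, locus)
  mother_idx <- match(table$mother_id, table$id)
  has_mother <- !is.na(mother_idx)
  offspring <- which(has_mother & table$sex == "F" & !is.na(al[, 1]) &
                       !is.na(al[, 2]))
  m_al <- al[mother_idx[offspring], , drop = FALSE]
  m_het <- !is.na(m_al[, 1]) & !is.na(m_al[, 2]) & m_al[, 1] != m_al[, 2]
  eligible <- offspring[m_het]
  n_excl <- sum(!m_het)
  if (n_excl > 0L) {
    warning(sprintf(
      "%s: %d offspring of homozygous or untyped mothers excluded",
      locus, n_excl
    ))
  }
  hom <- al[eligible, 1] == al[eligible, 2]
  Nt <- sum(!hom)
  No <- sum(hom)
  out <- data.frame(
    locus = locus, Nt = Nt, No = No,
    R = if (Nt + No > 0L) No / (Nt + No) else NA_real_,
    n_excluded = n_excl,
    stringsAsFactors = FALSE
  )
  class(out) <- c("locus_segregation_summary", "data.frame")
  out
}

#' Exact test of an observed transition rate against an expected rate
#'
#' Tests the observed homozygote/heterozygote split `(No, Nt)` against the
#' split expected under rate `r`. The default is a two-sided Fisher exact
#' test on the 2x2 table `[[No, Nt], [round(r*N), N - round(r*N)]]` with
#' `N = Nt + No` and half-up rounding; `method = "binomial"` instead tests
#' `No` successes in `N` trials against probability `r`.
#'
#' @param Nt,No Heterozygous / homozygous offspring counts (`Nt + No >= 1`).
#' @param r Expected transition rate in `[0, 1]`.
#' @param method `"fisher"` (default) or `"binomial"`.
#' @return The p-value.
#' @export
exact_test_vs_expected <- function(Nt, No, r, method = c("fisher", "binomial")) {
  method <- match.arg(method)
  if (Nt < 0 || No < 0 || Nt + No < 1) {
    stop_validation("need Nt, No >= 0 with Nt + No >= 1")
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1) {
    stop_validation("expected rate r must lie in [0, 1]")
  }
  N <- Nt + No
  if (method == "binomial") {
    return(as.numeric(stats::binom.test(No, N, p = r)$p.value))
  }
  e_hom <- round_half_up(r * N)
  tab <- matrix(c(No, e_hom, Nt, N - e_hom), nrow = 2)
  stats::fisher.test(tab)$p.value
}

#' Test observed transition rates against all five mechanisms
#'
#' For each locus summary, tests the observed `(Nt, No)` against the
#' expected rate of every mechanism. Point-valued mechanisms use their
#' constant (`apomixis` 0, `gamete_duplication` 1, `random_fusion` 1/3);
#' ranged mechanisms use the endpoint of their theoretical range closest to
#' the observed `R` (`central_fusion`: `R` clamped to `[0, 1/3]`;
#' `terminal_fusion`: `R` clamped to `[1/3, 1]`). Verdicts are `"***"`
#' when `p < alpha` and `"NS"` otherwise; the overall verdict is the set of
#' mechanisms not rejected at any locus.
#'
#' @param summaries One or more [transition_summary()] rows (rbind-able).
#' @param alpha Significance level; default 0.001 so verdicts map onto a
#'   `***` / `NS` dichotomy.
#' @param method Passed to [exact_test_vs_expected()].
#' @return A list with `per_locus` (data.frame: locus, Nt, No, R, mechanism,
#'   r_used, p_value, verdict) and `overall` (character vector of mechanisms
#'   compatible with every locus).
#' @export
classify_mechanism <- function(summaries, alpha = 0.001,
                               method = c("fisher", "binomial")) {
  method <- match.arg(method)
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) == 0L) stop_validation("no locus summaries supplied")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must lie in (0, 1)")
  }
  res <- do.call(rbind, lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    if (is.na(s$R)) {
      stop_validation(sprintf("locus %s has no eligible offspring", s$locus))
    }
    r_used <- c(
      apomixis = 0,
      gamete_duplication = 1,
      random_fusion = 1 / 3,
      central_fusion = min(max(s$R, 0), 1 / 3),
      terminal_fusion = min(max(s$R, 1 / 3), 1)
    )
    data.frame(
      locus = s$locus, Nt = s$Nt, No = s$No, R = s$R,
      mechanism = names(r_used), r_used = unname(r_used),
      p_value = vapply(r_used, function(r) {
        exact_test_vs_expected(s$Nt, s$No, r, method = method)
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  res$verdict <- ifelse(res$p_value < alpha, "***", "NS")
  ns_by_mech <- tapply(res$verdict == "NS", res$mechanism, all)
  overall <- MECHANISMS[MECHANISMS %in% names(ns_by_mech)[ns_by_mech]]
  list(per_locus = res, overall = overall)
}

#' Check clonal consistency of a genotype table
#'
#' Compares every diploid individual's multilocus genotype to a designated
#' founder genotype and reports the number of mismatching individuals and
#' the per-call genotyping error rate (mismatching locus calls / total
#' diploid locus calls). Under apomixis all generations should match the
#' founder exactly. Haploid males and missing calls are skipped.
#'
#' @param table A [genotype_table()].
#' @param founder_id Id of the founder row; defaults to the first row with
#'   no mother link.
#' @return List with `n_mismatch_individuals`, `n_mismatch_calls`,
#'   `n_calls`, `error_rate`, and `per_locus` (mismatch calls per locus).
#' @export
clonal_consistency <- function(table, founder_id = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(founder_id)) {
    cand <- which(table$mother_id == "." & table$sex == "F")
    if (length(cand) == 0L) stop_validation("no founder (motherless female) in table")
    founder_id <- table$id[cand[1]]
  }
  fi <- match(founder_id, table$id)
  if (is.na(fi)) stop_validation(sprintf("founder '%s' not in table", founder_id))
  loci <- gt_loci(table)
  rows <- which(table$sex == "F")
  per_locus <- stats::setNames(integer(length(loci)), loci)
  mism_ind <- logical(length(rows))
  n_calls <- 0L
  for (l in loci) {
    g <- table[[l]][rows]
    typed <- g != "."
    n_calls <- n_calls + sum(typed)
    bad <- typed & g != table[[l]][fi]
    per_locus[[l]] <- sum(bad)
    mism_ind <- mism_ind | bad
  }
  list(
    founder_id = founder_id,
    n_mismatch_individuals = sum(mism_ind),
    n_mismatch_calls = sum(per_locus),
    n_calls = n_calls,
    error_rate = if (n_calls > 0L) sum(per_locus) / n_calls else NA_real_,
    per_locus = per_locus
  )
}
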