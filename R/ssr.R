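#' SSR scanning configuration
#'
#' Thresholds for microsatellite detection: the minimum number of tandem
#' repeats per motif length (defaults 10, 6, 5, 5, 4, 4 for mono- through
#' hexanucleotide motifs), the maximum length of the single internal
#' interruption allowed in an imperfect locus, and the maximum spacer
#' between two reported loci that are merged into one compound locus.
#'
#' @param min_repeats Integer vector of length 6 (motif lengths 1..6).
#' @param max_interruption_bp Maximum interruption length (bp) for
#'   imperfect loci; default 3.
#' @param compound_max_spacer_bp Maximum spacer (bp) between loci merged
#'   into a compound locus; default 100.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(min_repeats = c(10L, 6L, 5L, 5L, 4L, 4L),
                        max_interruption_bp = 3L,
                        compound_max_spacer_bp = 100L) {
  if (length(min_repeats) != 6L || any(min_repeats < 2)) {
    stop_validation("min_repeats must give a count >= 2 for motif lengths 1..6")
  }
  if (max_interruption_bp < 0 || compound_max_spacer_bp < 0) {
    stop_validation("interruption and spacer lengths must be >= 0")
  }
  structure(
    list(
      min_repeats = as.integer(min_repeats),
      max_interruption_bp = as.integer(max_interruption_bp),
      compound_max_spacer_bp = as.integer(compound_max_spacer_bp)
    ),
    class = "scan_config"
  )
}

ssr_empty <- function() {
  data.frame(
    contig = character(), start = integer(), end = integer(),
    motif = character(), motif_length = integer(), repeat_count = integer(),
    category = character(), stringsAsFactors = FALSE
  )
}

# Is a motif primitive (not itself a tandem of a shorter unit)?
is_primitive_motif <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        unit == paste(rep(substr(unit, 1L, d), k / d), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

motifs_cyclic_equal <- function(u1, u2) {
  nchar(u1) == nchar(u2) && grepl(u2, paste0(u1, u1), fixed = TRUE)
}

check_sequence_chars <- function(s) {
  bad <- which(!s %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "illegal character '%s' at position %d (expected A/C/G/T/N)",
      s[bad[1]], bad[1]
    ))
  }
}

# Maximal tandem runs with primitive motifs and >= 2 repeats, found via the
# vectorised shifted-equality trick: s[i] == s[i+k] chains mark period-k
# regions; each maximal chain is truncated to complete repeats anchored at
# its start. 1-based inclusive coordinates.
find_tandem_runs <- function(s, min_count = 2L) {
  n <- length(s)
  out <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    eq <- s[seq_len(n - k)] == s[seq_len(n - k) + k] & s[seq_len(n - k)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      t <- r$lengths[j]
      count <- (t + k) %/% k
      if (count < min_count) next
      i <- starts[j]
      unit <- paste(s[i:(i + k - 1L)], collapse = "")
      if (!is_primitive_motif(unit)) next
      out[[length(out) + 1L]] <- data.frame(
        start = i, end = i + count * k - 1L, motif = unit,
        motif_length = k, repeat_count = count, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      motif_length = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Shared classification of raw runs into perfect / imperfect / compound
# loci. Rules:
#  * two runs of the same motif (up to cyclic rotation, same period)
#    separated by at most max_interruption_bp of called bases (an
#    interruption may not contain N) form one imperfect locus when their
#    joint repeat count meets the period's minimum; chains of three or
#    more interrupted runs are not a single imperfect locus and fall back to
#    their individual runs;
#  * a lone run meeting the minimum is a perfect locus;
#  * a locus strictly inside another locus is dropped;
#  * surviving loci separated by at most compound_max_spacer_bp merge into
#    one compound locus.
classify_runs <- function(runs, config, s) {
  if (nrow(runs) == 0L) return(ssr_empty())
  loci <- list()
  for (k in sort(unique(runs$motif_length))) {
    rk <- runs[runs$motif_length == k, , drop = FALSE]
    rk <- rk[order(rk$start), , drop = FALSE]
    m <- nrow(rk)
    # chain interrupted same-motif neighbours
    link <- logical(if (m > 1L) m - 1L else 0L)
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        gap <- rk$start[i + 1L] - rk$end[i] - 1L
        gap_has_n <- gap > 0L &&
          any(s[(rk$end[i] + 1L):(rk$start[i + 1L] - 1L)] == "N")
        link[i] <- gap <= config$max_interruption_bp && !gap_has_n &&
          motifs_cyclic_equal(rk$motif[i], rk$motif[i + 1L])
      }
    }
    grp <- cumsum(c(1L, !link))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) == 2L) {
        total <- sum(rk$repeat_count[idx])
        if (total >= config$min_repeats[k]) {
          loci[[length(loci) + 1L]] <- data.frame(
            start = rk$start[idx[1]], end = rk$end[idx[2]],
            motif = rk$motif[idx[1]], motif_length = k, repeat_count = total,
            category = "imperfect", stringsAsFactors = FALSE
          )
          next
        }
      }
      # lone runs, failed pairs, and >2-run chains: judge each run alone
      for (i in idx) {
        if (rk$repeat_count[i] >= config$min_repeats[k]) {
          loci[[length(loci) + 1L]] <- data.frame(
            start = rk$start[i], end = rk$end[i], motif = rk$motif[i],
            motif_length = k, repeat_count = rk$repeat_count[i],
            category = "perfect", stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(loci) == 0L) return(ssr_empty())
  loci <- do.call(rbind, loci)

  # drop loci strictly contained in a longer locus of another period
  span <- loci$end - loci$start
  loci <- loci[order(-span, loci$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!keep[i]) next
    inside <- keep & loci$start >= loci$start[i] & loci$end <= loci$end[i]
    inside[i] <- FALSE
    keep[inside] <- FALSE
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$start), , drop = FALSE]

  # compound merging
  if (nrow(loci) > 1L) {
    gap <- loci$start[-1L] - loci$end[-nrow(loci)] - 1L
    grp <- cumsum(c(1L, gap > config$compound_max_spacer_bp))
  } else {
    grp <- rep(1L, nrow(loci))
  }
  out <- lapply(unique(grp), function(g) {
    idx <- which(grp == g)
    if (length(idx) == 1L) return(loci[idx, , drop = FALSE])
    comp <- loci[idx, , drop = FALSE]
    data.frame(
      start = comp$start[1], end = comp$end[nrow(comp)],
      motif = paste(sprintf("(%s)%d", comp$motif, comp$repeat_count),
                    collapse = ""),
      motif_length = NA_integer_, repeat_count = NA_integer_,
      category = "compound", stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Scan a nucleotide sequence for microsatellites
#'
#' Detects maximal tandem repeats of 1-6 bp motifs meeting the per-motif
#' minimum repeat counts of `config`, reports each run at its shortest
#' period (a motif that is itself a tandem of a shorter motif is never
#' reported), classifies loci as perfect, imperfect (one internal
#' interruption of at most `max_interruption_bp` between two runs of the
#' same motif whose joint count meets the minimum), or compound (reported
#' loci separated by at most `compound_max_spacer_bp`). `N` breaks runs.
#' Coordinates are 0-based half-open.
#'
#' @param seq A single nucleotide string over `A/C/G/T/N` (case
#'   insensitive).
#' @param config A [scan_config()].
#' @return data.frame with columns `contig` (NA here), `start`, `end`,
#'   `motif`, `motif_length`, `repeat_count`, `category`.
#' @export
scan_sequence <- function(seq, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"), is.character(seq),
            length(seq) == 1L)
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  check_sequence_chars(s)
  runs <- find_tandem_runs(s)
  loci <- classify_runs(runs, config, s)
  if (nrow(loci) == 0L) return(ssr_empty())
  data.frame(
    contig = NA_character_,
    start = loci$start - 1L, end = loci$end,  # to 0-based half-open
    motif = loci$motif, motif_length = loci$motif_length,
    repeat_count = loci$repeat_count, category = loci$category,
    stringsAsFactors = FALSE
  )
}

#' Naive reference SSR scanner
#'
#' A deliberately simple O(n k r) scanner kept as an independent
#' cross-check of [scan_sequence()]: at every position and motif length it
#' counts repeats of the literal starting unit by direct comparison, keeps
#' left-maximal primitive runs, and applies the classification rules with
#' plain loops. Same output contract as [scan_sequence()].
#'
#' @inheritParams scan_sequence
#' @return data.frame as in [scan_sequence()].
#' @export
scan_sequence_naive <- function(seq, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  check_sequence_chars(s)
  n <- length(s)
  runs <- list()
  for (k in 1:6) {
    i <- 1L
    while (i + 2L * k - 1L <= n) {
      unit <- s[i:(i + k - 1L)]
      if (any(unit == "N")) { i <- i + 1L; next }
      # left-maximality: the period-k chain must not extend to i-1
      if (i > 1L && s[i - 1L] != "N" && s[i - 1L] == s[i + k - 1L]) {
        i <- i + 1L; next
      }
      count <- 1L
      while (i + (count + 1L) * k - 1L <= n &&
             all(s[(i + count * k):(i + (count + 1L) * k - 1L)] == unit)) {
        count <- count + 1L
      }
      ustr <- paste(unit, collapse = "")
      if (count >= 2L && is_primitive_motif(ustr)) {
        runs[[length(runs) + 1L]] <- data.frame(
          start = i, end = i + count * k - 1L, motif = ustr,
          motif_length = k, repeat_count = count, stringsAsFactors = FALSE
        )
      }
      i <- i + 1L
    }
  }
  runs <- if (length(runs) == 0L) {
    data.frame(start = integer(), end = integer(), motif = character(),
               motif_length = integer(), repeat_count = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, runs)
  }
  loci <- classify_runs(runs, config, s)
  if (nrow(loci) == 0L) return(ssr_empty())
  data.frame(
    contig = NA_character_,
    start = loci$start - 1L, end = loci$end,
    motif = loci$motif, motif_length = loci$motif_length,
    repeat_count = loci$repeat_count, category = loci$category,
    stringsAsFactors = FALSE
  )
}

#' Scan a FASTA file for microsatellites
#'
#' Runs [scan_sequence()] on every contig of a FASTA file and summarises
#' the results over contigs containing at least one SSR.
#'
#' @param path Path to a FASTA file.
#' @param config A [scan_config()].
#' @return List with `loci` (data.frame over all contigs) and `summary`
#'   (see [summarize_ssr()]).
#' @export
scan_fasta <- function(path, config = scan_config()) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop_validation(sprintf("%s: empty FASTA", path))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop_validation(sprintf(
      "duplicate contig id: %s", ids[duplicated(ids)][1]
    ))
  }
  loci <- lapply(seq_along(seqs), function(i) {
    li <- scan_sequence(as.character(seqs[[i]]), config)
    if (nrow(li) > 0L) li$contig <- ids[i]
    li
  })
  loci <- do.call(rbind, loci)
  n_with <- length(unique(loci$contig))
  list(
    loci = loci,
    summary = if (n_with > 0L) summarize_ssr(loci, n_with) else NULL,
    n_contigs = length(seqs),
    n_contigs_with_ssr = n_with
  )
}

#' Summarise SSR loci
#'
#' Category counts (perfect / compound / imperfect) and, for perfect loci,
#' per-motif-length counts with frequencies expressed as percent of the
#' contigs containing SSRs, reported to two decimals.
#'
#' @param loci data.frame of SSR loci (as from [scan_sequence()] or
#'   [scan_fasta()]).
#' @param n_contigs_with_ssr Number of contigs containing at least one SSR
#'   (the denominator for the frequencies).
#' @return List with `n_loci`, `n_contigs_with_ssr`, `category_counts`,
#'   `perfect_by_motif_length` (counts, named `"1"`..`"6"`), and
#'   `perfect_freq_pct`.
#' @export
summarize_ssr <- function(loci, n_contigs_with_ssr) {
  if (n_contigs_with_ssr < 1) {
    stop_validation("n_contigs_with_ssr must be >= 1")
  }
  cat_counts <- vapply(c("perfect", "compound", "imperfect"),
                       function(cc) sum(loci$category == cc), integer(1))
  perfect <- loci[loci$category == "perfect", , drop = FALSE]
  by_len <- vapply(1:6, function(k) sum(perfect$motif_length == k), integer(1))
  names(by_len) <- as.character(1:6)
  list(
    n_loci = nrow(loci),
    n_contigs_with_ssr = n_contigs_with_ssr,
    category_counts = cat_counts,
    perfect_by_motif_length = by_len,
    perfect_freq_pct = round(by_len / n_contigs_with_ssr * 100, 2)
  )
}
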