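#' Construct a genotype table
#'
#' The central tabular container of the pipeline: one row per individual
#' with columns `id`, `generation`, `mother_id` (`"."` for none), `sex`
#' (`"F"` diploid female, `"M"` haploid male), followed by one column per
#' locus holding `"a/b"` for diploids, `"a"` for haploid males, and `"."`
#' for missing calls. Allele pairs are unordered; they are serialised with
#' the labels sorted so outputs are canonical and diffable.
#'
#' @param df A data.frame with the columns above.
#' @param loci Character vector of locus column names; defaults to all
#'   columns after the four metadata columns.
#' @return An object of class `genotype_table` (a data.frame with a `loci`
#'   attribute).
#' @export
genotype_table <- function(df, loci = NULL) {
  meta <- c("id", "generation", "mother_id", "sex")
  if (!all(meta %in% names(df))) {
    stop_validation(sprintf(
      "genotype table needs columns: %s", paste(meta, collapse = ", ")
    ))
  }
  if (is.null(loci)) loci <- setdiff(names(df), meta)
  if (length(loci) == 0L) stop_validation("genotype table has no locus columns")
  if (anyDuplicated(df$id)) stop_validation("duplicate individual ids")
  known <- c(".", df$id)
  dangling <- setdiff(unique(df$mother_id), known)
  if (length(dangling) > 0L) {
    stop_validation(sprintf(
      "mother_id values with no matching individual: %s",
      paste(dangling, collapse = ", ")
    ))
  }
  if (!all(df$sex %in% c("F", "M"))) {
    stop_validation("sex must be 'F' (diploid) or 'M' (haploid)")
  }
  for (l in loci) {
    g <- df[[l]]
    bad <- which(!grepl("^(\\.|[^/]+|[^/]+/[^/]+)$", g))
    if (length(bad) > 0L) {
      stop_validation(sprintf(
        "malformed genotype in column %s, row %d: '%s'", l, bad[1], g[bad[1]]
      ))
    }
    diploid <- df$sex == "F" & g != "."
    n_alleles <- lengths(strsplit(g, "/", fixed = TRUE))
    if (any(diploid & n_alleles != 2L)) {
      i <- which(diploid & n_alleles != 2L)[1]
      stop_validation(sprintf(
        "diploid row %d ('%s') needs two alleles at %s, got '%s'",
        i, df$id[i], l, g[i]
      ))
    }
    if (any(!diploid & df$sex == "M" & g != "." & n_alleles != 1L)) {
      i <- which(df$sex == "M" & g != "." & n_alleles != 1L)[1]
      stop_validation(sprintf(
        "haploid row %d ('%s') must carry a single allele at %s, got '%s'",
        i, df$id[i], l, g[i]
      ))
    }
    # canonical serialisation: alleles sorted within the pair
    df[[l]] <- canonical_genotype(g)
  }
  df <- as.data.frame(df[, c(meta, loci)], stringsAsFactors = FALSE)
  structure(df, loci = loci, class = c("genotype_table", "data.frame"))
}

canonical_genotype <- function(g) {
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(parts, function(p) paste(sort(p), collapse = "/"), character(1))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table: %d individuals, %d loci (%s)>\n",
              nrow(x), length(attr(x, "loci")),
              paste(attr(x, "loci"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Locus names of a genotype table
#' @param table A `genotype_table`.
#' @return Character vector of locus column names.
#' @export
gt_loci <- function(table) attr(table, "loci")

# Split one locus column into an n x 2 allele matrix (haploids: second
# allele NA; missing calls: both NA).
gt_alleles <- function(table, locus) {
  if (!locus %in% gt_loci(table)) {
    stop_validation(sprintf("locus '%s' not in table", locus))
  }
  g <- table[[locus]]
  parts <- strsplit(g, "/", fixed = TRUE)
  a1 <- vapply(parts, `[`, character(1), 1L)
  a2 <- vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_,
               character(1))
  a1[g == "."] <- NA_character_
  cbind(a1, a2, deparse.level = 0)
}

#' Read a genotype table from TSV
#'
#' Expects a tab-separated file with header
#' `id  generation  mother_id  sex  <locus1> <locus2> ...`; allele pairs as
#' `"a/b"`, haploid males as `"a"`, missing calls as `"."`.
#'
#' @param path Path to the TSV file.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop_validation(sprintf("%s: need a header line and at least one row", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol <- length(header)
  ragged <- which(lengths(fields[-1]) != ncol)
  if (length(ragged) > 0L) {
    stop_validation(sprintf(
      "%s: line %d has %d fields, expected %d",
      path, ragged[1] + 1L, lengths(fields[-1])[ragged[1]], ncol
    ))
  }
  df <- as.data.frame(
    do.call(rbind, fields[-1]), stringsAsFactors = FALSE
  )
  names(df) <- header
  genotype_table(df)
}

#' Write a genotype table to TSV
#'
#' @param table A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
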