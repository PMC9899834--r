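#' Write a mechanism-test report
#'
#' Serialises the output of [classify_mechanism()] as a TSV (one row per
#' locus x mechanism with Nt, No, R, r_used, p, verdict) and, optionally,
#' a JSON document that also carries the overall verdict.
#'
#' @param result List from [classify_mechanism()].
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return `result`, invisibly.
#' @export
write_mechanism_report <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(result$per_locus, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_locus = result$per_locus, overall = result$overall),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(result)
}

#' Write an SSR locus table and summary
#'
#' @param scan Result of [scan_fasta()].
#' @param tsv_path Locus table output (contig, start, end, motif,
#'   motif_length, repeat_count, category; 0-based half-open coordinates).
#' @param json_path Summary output.
#' @return `scan`, invisibly.
#' @export
write_ssr_report <- function(scan, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(scan$loci, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(scan$summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(scan)
}

#' Write a run manifest
#'
#' Records the package version, seed and parameters of a run as JSON so
#' any output can be regenerated bit-for-bit.
#'
#' @param path Output path.
#' @param seed Integer seed used by the run.
#' @param params Named list of run parameters.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, params = list()) {
  jsonlite::write_json(
    list(
      package = "thelytools",
      version = as.character(utils::packageVersion("thelytools")),
      seed = check_seed(seed),
      params = params,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
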