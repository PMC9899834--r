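#' Centromeric index
#'
#' `CI = 100 * short_arm / (short_arm + long_arm)`, in `(0, 50]` since by
#' convention the short arm is no longer than the long arm.
#'
#' @param short_arm,long_arm Positive arm lengths (any common unit);
#'   vectorised.
#' @return Centromeric index values.
#' @export
centromeric_index <- function(short_arm, long_arm) {
  if (any(short_arm <= 0) || any(long_arm <= 0)) {
    stop_validation("arm lengths must be positive")
  }
  if (any(short_arm > long_arm + 1e-9)) {
    stop_validation("short arm must not exceed long arm")
  }
  100 * short_arm / (short_arm + long_arm)
}

#' Classify a chromosome from its centromeric index
#'
#' Metacentric (`M`) for `CI >= 37.5`, submetacentric (`SM`) for
#' `25 <= CI < 37.5`, acrocentric (`A`) for `CI < 25`; boundary values go
#' to the higher class.
#'
#' @param ci Centromeric index in `(0, 50]`; vectorised.
#' @return Character vector of `"M"`, `"SM"`, `"A"`.
#' @export
classify_chromosome <- function(ci) {
  if (any(is.na(ci)) || any(ci <= 0) || any(ci > 50 + 1e-9)) {
    stop_validation("centromeric index must lie in (0, 50]")
  }
  ifelse(ci >= 37.5, "M", ifelse(ci >= 25, "SM", "A"))
}

check_measurements <- function(measurements) {
  need <- c("pair_id", "replicate", "short_arm", "long_arm")
  if (!all(need %in% names(measurements))) {
    stop_validation(sprintf(
      "measurements need columns: %s", paste(need, collapse = ", ")
    ))
  }
  if (any(measurements$short_arm <= 0) || any(measurements$long_arm <= 0)) {
    stop_validation("arm lengths must be positive")
  }
  if (any(measurements$short_arm > measurements$long_arm + 1e-9)) {
    stop_validation("short arm must not exceed long arm")
  }
  measurements
}

#' Relative chromosome lengths
#'
#' For each cell (replicate), the total length of each chromosome pair is
#' expressed as a percentage of the haploid complement's total length
#' (`RL = 100 * (short + long) / sum over pairs`), then averaged over
#' cells. Cells missing any pair are excluded with a warning.
#'
#' @param measurements data.frame with columns `pair_id`, `replicate`,
#'   `short_arm`, `long_arm` (one row per pair per cell).
#' @return data.frame: `pair_id`, `RL_mean`, `RL_sd`, `n_cells`.
#' @export
relative_length <- function(measurements) {
  measurements <- check_measurements(measurements)
  pairs <- sort(unique(measurements$pair_id))
  complete <- vapply(split(measurements, measurements$replicate),
                     function(d) setequal(d$pair_id, pairs), logical(1))
  if (any(!complete)) {
    warning(sprintf("%d incomplete cell(s) excluded", sum(!complete)))
    keep <- names(complete)[complete]
    measurements <- measurements[measurements$replicate %in% keep, ]
    if (nrow(measurements) == 0L) stop_validation("no complete cells")
  }
  total <- measurements$short_arm + measurements$long_arm
  cell_sum <- stats::ave(total, measurements$replicate, FUN = sum)
  rl <- 100 * total / cell_sum
  agg <- function(f) tapply(rl, measurements$pair_id, f)
  data.frame(
    pair_id = pairs,
    RL_mean = as.numeric(agg(mean)[as.character(pairs)]),
    RL_sd = as.numeric(agg(stats::sd)[as.character(pairs)]),
    n_cells = as.integer(tapply(rl, measurements$pair_id, length)[as.character(pairs)]),
    row.names = NULL
  )
}

#' Full karyotype report
#'
#' Per-pair mean and standard deviation of relative length and centromeric
#' index, class (`M`/`SM`/`A`) from the mean CI, the diploid number
#' `2n = 2 x pairs`, and a karyotype formula such as
#' `"2n = 10 = 8M + 2SM"`.
#'
#' @inheritParams relative_length
#' @return List of class `karyotype_report`: `table` (pair_id, RL_mean,
#'   RL_sd, CI_mean, CI_sd, class), `two_n`, `formula`.
#' @export
karyotype_report <- function(measurements) {
  measurements <- check_measurements(measurements)
  rl <- relative_length(measurements)
  ci <- centromeric_index(measurements$short_arm, measurements$long_arm)
  ci_mean <- tapply(ci, measurements$pair_id, mean)
  ci_sd <- tapply(ci, measurements$pair_id, stats::sd)
  ord <- as.character(rl$pair_id)
  tab <- data.frame(
    pair_id = rl$pair_id,
    RL_mean = rl$RL_mean, RL_sd = rl$RL_sd,
    CI_mean = as.numeric(ci_mean[ord]), CI_sd = as.numeric(ci_sd[ord]),
    row.names = NULL
  )
  tab$class <- classify_chromosome(tab$CI_mean)
  two_n <- 2L * nrow(tab)
  cls <- table(factor(tab$class, levels = c("M", "SM", "A")))
  parts <- sprintf("%d%s", 2L * as.integer(cls[cls > 0]),
                   names(cls)[cls > 0])
  structure(
    list(
      table = tab,
      two_n = two_n,
      formula = sprintf("2n = %d = %s", two_n, paste(parts, collapse = " + "))
    ),
    class = "karyotype_report"
  )
}

#' @export
print.karyotype_report <- function(x, ...) {
  cat(sprintf("<karyotype_report: %s>\n", x$formula))
  print(x$table, digits = 4)
  invisible(x)
}
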