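#' @keywords internal
"_PACKAGE"

# Round to nearest integer with ties going up (round() in R rounds half to
# even, which is not what contingency-table construction wants here).
round_half_up <- function(x) floor(x + 0.5)

# Stop with a classed condition so callers/tests can distinguish validation
# failures from programming errors.
stop_validation <- function(msg, class = "thelytools_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# All five diploidy-restoration modes handled by the pipeline. Apomixis is
# listed first: it bypasses meiosis entirely.
MECHANISMS <- c(
  "apomixis", "gamete_duplication", "terminal_fusion",
  "central_fusion", "random_fusion"
)

check_mechanism <- function(mech) {
  if (!is.character(mech) || length(mech) != 1L || !mech %in% MECHANISMS) {
    stop_validation(sprintf(
      "mechanism must be one of: %s", paste(MECHANISMS, collapse = ", ")
    ))
  }
  mech
}

# y is the per-meiosis probability of second-division segregation at a locus
# (a crossover between centromere and locus). Biologically y <= 2/3; unit
# tests may use the permissive range [0, 1].
check_y <- function(y, permissive = FALSE) {
  hi <- if (permissive) 1 else 2 / 3
  if (!is.numeric(y) || anyNA(y) || any(y < 0) || any(y > hi + 1e-12)) {
    stop_validation(sprintf(
      "second-division segregation probability y must lie in [0, %s]",
      if (permissive) "1" else "2/3"
    ))
  }
  y
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("seed must be a single integer")
  }
  as.integer(seed)
}
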