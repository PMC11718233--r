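# Shared helpers: display rounding, derived RNG streams, JSONL IO.

#' Half-away-from-zero rounding
#'
#' Display rounding for reports: 0.05 rounds up to 0.1 at one decimal, the
#' convention used for printed percentages (base `round()` is
#' round-half-even). Machine outputs keep full precision; this is applied
#' only to display columns.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Derived per-unit RNG stream: one global seed plus a unit id (e.g. a
# person_id) map to an independent substream, so enlarging a population
# never reshuffles existing units. Kept below 2^31 - 1.
derived_seed <- function(seed, unit) {
  (as.numeric(seed) * 48271 + as.numeric(unit) * 16807) %% 2147483647
}

with_derived_seed <- function(seed, unit, expr) {
  set.seed(derived_seed(seed, unit))
  expr
}

# JSONL: one JSON object per line, written atomically per call.
write_jsonl <- function(records, path, append = FALSE) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  null = "null")),
    character(1))
  con <- file(path, if (append) "ab" else "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}
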