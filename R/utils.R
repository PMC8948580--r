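#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), matching how the headline
#' percentages are reported; base R's round() uses banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
# Each synthetic-data generator draws from its own stream so adding one
# generator call never shifts another's output.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Strip a trailing "-<digits>" GEM-well suffix from 10x cell barcodes so that
# grouping never depends on it; sample identity comes from sample_id alone.
stripBarcodeSuffix <- function(x) sub("-[0-9]+$", "", x)

# Parse the productive flag as written by various tools: TRUE/True/true/T,
# FALSE/False/false/F/None, case-insensitive.
parseProductive <- function(x) {
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO", "NONE", "NA", "")] <- FALSE
  if (anyNA(out))
    stop("unrecognized productive flag value(s): ",
      paste(unique(v[is.na(out)]), collapse = ", "))
  out
}

# write.table with the fixed conventions used throughout: TSV/CSV, LF line
# endings, no quotes, no row names -- bit-reproducible given identical input.
writeFlatTable <- function(df, path, sep = "\t") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE,
    row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

writeJSONReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(path)
}
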