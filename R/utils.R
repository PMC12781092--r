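## Internal helpers shared across modules.

#' Canonical undirected edge key
#'
#' @param u,v Endpoint gene identifiers (vectorized).
#' @return `"min|max"` string key, order-independent.
#' @keywords internal
edgeKey <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

## Canonicalize an edge data.frame so u <= v lexicographically.
canonicalizeEdges <- function(df) {
  swap <- df$u > df$v
  if (any(swap)) {
    tmp <- df$u[swap]
    df$u[swap] <- df$v[swap]
    df$v[swap] <- tmp
  }
  df
}

## Scalar argument checks -------------------------------------------------

assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf,
                                strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("'%s' must be a single finite number in %s%g, %g%s",
                 name, if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"), call. = FALSE)
  invisible(x)
}

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

## Read a TSV allowing an optional single header line starting with "#".
## Returns a character matrix of fields plus the 1-based line number of
## each data row (for error messages).
readTsvLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) && startsWith(lines[1], "#")) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  list(fields = fields, lineno = lineno)
}

writeTsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Seeded evaluation that restores the caller's RNG state.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
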