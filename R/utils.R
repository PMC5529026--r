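# Internal helpers: seeded evaluation, seed fan-out, TSV I/O with a
# provenance comment line.

# Evaluate `expr` under set.seed(seed) and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific substream seed from a master seed and a label.
# Multiplicative mixing in double precision, reduced mod 2^31 - 1 so the
# result is always a valid 32-bit seed; stable across platforms.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 69069 + h * 30269 + 1013) %% 2147483647)
}

#' Write a table as TSV with a provenance comment header
#'
#' All pipeline tables are written as plain TSV preceded by a single
#' `#`-prefixed comment line recording provenance (typically the seed).
#'
#' @param x a data.frame.
#' @param path output file path.
#' @param comment character scalar placed after `# ` on the first line,
#'   or `NULL` for no comment line.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV, skipping `#` comment lines
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
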